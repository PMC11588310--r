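#' Quantification parameters: volume filter, overlap proxy, channel pairs
#'
#' @param min_volume segments strictly smaller than this volume (um^3) are
#'   eliminated; the default 0.2 um^3 removes sub-resolution debris.
#' @param overlap_threshold a query punctum counts as co-occurring when
#'   strictly more than this fraction of its voxels lie inside the target
#'   channel's segments (default 0.9, i.e. ">90%" as a proxy for
#'   co-occurrence).
#' @param ordered_pairs list of `c(query, target)` channel-label pairs. The
#'   default is the four ratios reported for autophagosome biogenesis:
#'   ATG9-vs-ATG8 in both directions and each autophagosome marker against
#'   the PLVAC marker FYVE.
#' @param overlap_relative_to overlap is measured against the query punctum's
#'   own volume (`"query"`, default — the organelle targets are much larger
#'   than the puncta, so this is the direction under which >90% is
#'   attainable) or the smaller of the two volumes (`"smaller"`).
#' @return An object of class `QuantificationConfig`.
#' @export
quant_config <- function(min_volume = 0.2,
                         overlap_threshold = 0.9,
                         ordered_pairs = list(c("ATG9", "ATG8"),
                                              c("ATG8", "ATG9"),
                                              c("ATG9", "FYVE"),
                                              c("ATG8", "FYVE")),
                         overlap_relative_to = c("query", "smaller")) {
  overlap_relative_to <- match.arg(overlap_relative_to)
  if (min_volume < 0) stop("min_volume must be >= 0")
  if (overlap_threshold <= 0 || overlap_threshold > 1) {
    stop("overlap_threshold must be in (0, 1]")
  }
  if (!all(vapply(ordered_pairs, length, 1L) == 2L)) {
    stop("ordered_pairs must be a list of (query, target) label pairs")
  }
  structure(
    list(min_volume = min_volume,
         overlap_threshold = overlap_threshold,
         ordered_pairs = ordered_pairs,
         overlap_relative_to = overlap_relative_to),
    class = "QuantificationConfig"
  )
}

#' Eliminate segments smaller than the volume threshold
#'
#' Retains exactly the segments whose volume is at least `cfg$min_volume`
#' ("smaller than" read strictly: a segment exactly at the threshold is
#' kept). Order is preserved; an empty input yields an empty output.
#'
#' @param segments a segments `data.frame` from [segment_blobs()] or
#'   [detect_puncta()].
#' @param cfg a [quant_config()].
#' @return the filtered segments.
#' @export
filter_by_volume <- function(segments, cfg = quant_config()) {
  if (!"volume" %in% names(segments)) stop("segments must carry volumes")
  keep_attrs(segments[segments$volume >= cfg$min_volume - 1e-12, ,
                      drop = FALSE], segments)
}

keep_attrs <- function(out, src) {
  attr(out, "grid_dim") <- attr(src, "grid_dim")
  attr(out, "spacing") <- attr(src, "spacing")
  out
}

#' Fraction of a query segment covered by target-channel segments
#'
#' Returns `|query voxels intersected with the union of target segment
#' voxels| / |query voxels|`. Query and targets must live on the same voxel
#' grid and timepoint.
#'
#' @param query a one-row segments `data.frame` (one punctum).
#' @param target_segments segments of the target channel.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(query, target_segments) {
  if (nrow(query) != 1) stop("'query' must be a single segment (one row)")
  gq <- attr(query, "grid_dim")
  gt <- attr(target_segments, "grid_dim")
  if (!is.null(gq) && !is.null(gt) && !identical(gq, gt)) {
    stop("query and target segments live on different grids")
  }
  tseg <- target_segments[target_segments$timepoint == query$timepoint, ,
                          drop = FALSE]
  if (nrow(tseg) < nrow(target_segments) &&
      !all(target_segments$timepoint == query$timepoint)) {
    # mixed timepoints in targets are fine; a target table entirely from a
    # different timepoint is a caller error
    if (nrow(tseg) == 0 && nrow(target_segments) > 0) {
      stop("no target segments share the query's timepoint")
    }
  }
  if (nrow(tseg) == 0) return(0)
  tvox <- unlist(tseg$voxels)
  qvox <- query$voxels[[1]]
  sum(qvox %in% tvox) / length(qvox)
}

#' Per-cyst co-occurrence ratios, counts and mean object volumes
#'
#' For each ordered channel pair, counts the query puncta whose
#' [overlap_fraction()] against the target channel strictly exceeds the
#' overlap threshold, and divides by the total number of query puncta. A
#' query punctum overlapping several target segments is counted once (union
#' semantics). Segments are pooled across timepoints — overlap is evaluated
#' within each timepoint, counts are summed over the series — yielding one
#' ratio per cyst. Per-channel puncta counts and mean object volumes are
#' reported alongside. Pairs with no query puncta get an `NA` ratio
#' (undefined, never zero).
#'
#' @param segments a volume-filtered segments `data.frame` covering all
#'   channels of one cyst (see [filter_by_volume()]).
#' @param cfg a [quant_config()].
#' @param cyst_id,condition identifiers carried into the result.
#' @return An object of class `CystQuantResult`: list with `cyst_id`,
#'   `condition`, named `counts`, named `mean_volumes`, and a `pairs`
#'   data.frame (`query`, `target`, `numerator`, `denominator`, `ratio`).
#' @export
cooccurrence_ratios <- function(segments, cfg = quant_config(),
                                cyst_id = NA, condition = NA_character_) {
  channels <- unique(unlist(cfg$ordered_pairs))
  counts <- setNames(integer(length(channels)), channels)
  mvol <- setNames(rep(NA_real_, length(channels)), channels)
  for (ch in channels) {
    chseg <- segments[segments$channel == ch, , drop = FALSE]
    counts[ch] <- nrow(chseg)
    mvol[ch] <- mean_object_volume(chseg)
  }
  rows <- lapply(cfg$ordered_pairs, function(pr) {
    q <- pr[1]; tg <- pr[2]
    qs <- segments[segments$channel == q, , drop = FALSE]
    ts <- segments[segments$channel == tg, , drop = FALSE]
    den <- nrow(qs)
    num <- 0L
    if (den > 0 && nrow(ts) > 0) {
      for (t in unique(qs$timepoint)) {
        tvox <- unlist(ts$voxels[ts$timepoint == t])
        if (length(tvox) == 0) next
        qt <- qs[qs$timepoint == t, , drop = FALSE]
        for (i in seq_len(nrow(qt))) {
          qvox <- qt$voxels[[i]]
          denom_vox <- if (cfg$overlap_relative_to == "query") {
            length(qvox)
          } else {
            min(length(qvox), sum(ts$voxel_count[ts$timepoint == t]))
          }
          frac <- sum(qvox %in% tvox) / denom_vox
          if (frac > cfg$overlap_threshold) num <- num + 1L
        }
      }
    }
    data.frame(query = q, target = tg, numerator = num, denominator = den,
               ratio = if (den > 0) num / den else NA_real_)
  })
  structure(
    list(cyst_id = cyst_id, condition = condition, counts = counts,
         mean_volumes = mvol, pairs = do.call(rbind, rows)),
    class = "CystQuantResult"
  )
}

#' @export
print.CystQuantResult <- function(x, ...) {
  cat("CystQuantResult", if (!is.na(x$cyst_id)) paste0("(cyst ", x$cyst_id, ")"),
      "\n  counts:", paste(names(x$counts), x$counts, collapse = ", "), "\n")
  cat("  mean volumes (um^3):",
      paste(names(x$mean_volumes), signif(x$mean_volumes, 3),
            collapse = ", "), "\n")
  p <- x$pairs
  cat("  ratios:", paste(paste0(p$query, ">", p$target), "=",
                         signif(p$ratio, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a CystQuantResult into one table row
#' @param x a `CystQuantResult`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a one-row `data.frame` with count, mean-volume and ratio columns.
#' @export
as.data.frame.CystQuantResult <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  out <- data.frame(cyst_id = x$cyst_id, condition = x$condition)
  for (ch in names(x$counts)) out[[paste0("count_", ch)]] <- x$counts[[ch]]
  for (ch in names(x$mean_volumes)) {
    out[[paste0("meanvol_", ch)]] <- x$mean_volumes[[ch]]
  }
  for (i in seq_len(nrow(x$pairs))) {
    out[[paste0("ratio_", x$pairs$query[i], "_", x$pairs$target[i])]] <-
      x$pairs$ratio[i]
  }
  out
}

#' Mean object volume of a set of segments
#'
#' Arithmetic mean of segment volumes in um^3; `NA` (undefined) for an empty
#' input, never zero — an absent population is not a measurement of size.
#'
#' @param segments segments from one channel of one cyst.
#' @return mean volume in um^3, or `NA_real_`.
#' @export
mean_object_volume <- function(segments) {
  if (nrow(segments) == 0) return(NA_real_)
  mean(segments$volume)
}
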