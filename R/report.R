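#' Paired two-sided Student's t-test on replicate means
#'
#' Thin wrapper around [stats::t.test()] with explicit handling of the
#' degenerate cases that replicate-level imaging data can produce: if every
#' paired difference is exactly zero the test is reported as `t = 0, p = 1`;
#' if the differences have zero variance but a nonzero mean the test is
#' reported at its degenerate limit (`t = +/-Inf`, `p = 0`) with a warning.
#'
#' @param treated,vehicle equal-length paired numeric vectors (one value per
#'   replicate), `n >= 2`.
#' @return list with elements `t` and `p`.
#' @export
paired_t_test <- function(treated, vehicle) {
  if (length(treated) != length(vehicle)) {
    stop("paired vectors must have equal length")
  }
  if (length(treated) < 2) stop("paired t-test needs at least 2 replicates")
  if (anyNA(treated) || anyNA(vehicle)) stop("paired values must be complete")
  d <- treated - vehicle
  se <- sd(d) / sqrt(length(d))
  # same degeneracy criterion as stats::t.test ("data are essentially
  # constant"), handled explicitly instead of erroring
  if (sd(d) == 0 || se < 10 * .Machine$double.eps * abs(mean(d))) {
    if (mean(d) == 0) return(list(t = 0, p = 1))
    warning("zero variance of paired differences; reporting the degenerate ",
            "limit t = ", ifelse(mean(d) > 0, "Inf", "-Inf"), ", p = 0")
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- t.test(treated, vehicle, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Aggregate per-cyst metrics by replicate and compare conditions
#'
#' Computes, for every numeric metric in the per-cyst table, the
#' replicate-level means within each condition (undefined per-cyst values are
#' ignored), then the overall mean and SD of those replicate means, and a
#' paired two-sided t-test between conditions with replicates as the pairing
#' unit — statistics are computed on `n = replicates`, not on pooled cysts.
#' A replicate whose cysts are all undefined for a metric is excluded for
#' that metric (with a warning) and the pairing shrinks accordingly.
#'
#' @param per_cyst_table `data.frame` with columns `condition`, `replicate`
#'   and one column per metric (e.g. the output of [run_pipeline()]).
#' @param conditions length-2 character vector `c(reference, treatment)`;
#'   defaults to the order of first appearance. The test statistic is
#'   oriented as treatment minus reference.
#' @param metrics metric column names; default: all numeric columns other
#'   than identifiers.
#' @return An object of class `ConditionSummary`: a `data.frame` with one row
#'   per metric (`metric`, per-condition `mean`/`sd` of replicate means,
#'   `n_replicates`, `t`, `p`), with the replicate-mean matrix attached as
#'   attribute `replicate_means`.
#' @export
aggregate_replicates <- function(per_cyst_table, conditions = NULL,
                                 metrics = NULL) {
  tbl <- per_cyst_table
  stopifnot(all(c("condition", "replicate") %in% names(tbl)))
  if (is.null(conditions)) conditions <- unique(as.character(tbl$condition))
  if (length(conditions) != 2) {
    stop("exactly two conditions are required; got: ",
         paste(conditions, collapse = ", "))
  }
  tbl <- tbl[tbl$condition %in% conditions, , drop = FALSE]
  reps <- sort(unique(tbl$replicate))
  for (cond in conditions) {
    missing <- setdiff(reps, unique(tbl$replicate[tbl$condition == cond]))
    if (length(missing) > 0) {
      stop("replicate(s) ", paste(missing, collapse = ", "),
           " missing condition '", cond, "'; pairing is broken")
    }
  }
  if (is.null(metrics)) {
    skip <- c("condition", "replicate", "cyst_id", "seed")
    metrics <- names(tbl)[vapply(tbl, is.numeric, TRUE)]
    metrics <- setdiff(metrics, skip)
  }
  rep_means <- list()
  rows <- lapply(metrics, function(m) {
    mm <- matrix(NA_real_, length(reps), 2,
                 dimnames = list(as.character(reps), conditions))
    for (ci in 1:2) {
      for (ri in seq_along(reps)) {
        v <- tbl[[m]][tbl$condition == conditions[ci] &
                        tbl$replicate == reps[ri]]
        v <- v[!is.na(v)]
        mm[ri, ci] <- if (length(v) > 0) mean(v) else NA_real_
      }
    }
    ok <- stats::complete.cases(mm)
    if (any(!ok)) {
      warning("metric '", m, "': replicate(s) ",
              paste(rownames(mm)[!ok], collapse = ", "),
              " have no defined values in one condition and are excluded")
    }
    mm_ok <- mm[ok, , drop = FALSE]
    rep_means[[m]] <<- mm
    ht <- if (nrow(mm_ok) >= 2) {
      paired_t_test(mm_ok[, 2], mm_ok[, 1])
    } else {
      list(t = NA_real_, p = NA_real_)
    }
    out <- data.frame(metric = m,
                      n_replicates = nrow(mm_ok),
                      t = ht$t, p = ht$p)
    out[[paste0("mean_", conditions[1])]] <- mean(mm_ok[, 1])
    out[[paste0("sd_", conditions[1])]] <- sd(mm_ok[, 1])
    out[[paste0("mean_", conditions[2])]] <- mean(mm_ok[, 2])
    out[[paste0("sd_", conditions[2])]] <- sd(mm_ok[, 2])
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "replicate_means") <- rep_means
  class(out) <- c("ConditionSummary", "data.frame")
  out
}

#' Run the full quantification pipeline on simulated cysts
#'
#' End-to-end orchestration of the four analysis stages over a simulated
#' experiment with two arms (e.g. vehicle vs auxin-induced knockdown). Per
#' cyst: a matched control acquisition is simulated and used to estimate the
#' channel-1 background ([estimate_background()]); the background is
#' subtracted ([subtract_background()]); the volume is deskewed if it carries
#' a skew angle; the cyst is segmented ([segment_cyst()]); puncta are
#' enhanced and segmented per channel within the cyst ([detect_puncta()]);
#' segments are volume-filtered and turned into co-occurrence ratios and mean
#' object volumes ([cooccurrence_ratios()]). Per-cyst rows are then
#' aggregated by replicate and the two arms compared with paired t-tests
#' ([aggregate_replicates()]). Deterministic given `seed`.
#'
#' @param params base [simulation_params()] describing the vehicle arm.
#' @param n_cysts cysts per condition.
#' @param n_replicates biological replicates; cysts are assigned to
#'   replicates round-robin and both conditions share the replicate
#'   structure.
#' @param conditions named logical vector: names are condition labels, values
#'   say whether [apply_knockdown()] is applied to that arm. Use a single
#'   `FALSE` entry for a one-arm run (no summary is computed).
#' @param det_cfg,quant_cfg,bg_cfg detection, quantification and
#'   background-estimation configurations.
#' @param fyve_det_cfg detection configuration for the FYVE channel; the
#'   default adds a coarse enhancement scale matched to the large organelle
#'   bodies so they are segmented as solid objects.
#' @param bg_min_volume volume filter for control segments in background
#'   estimation.
#' @param seed master seed; per-cyst simulation seeds are derived from it.
#' @param out_dir optional directory; when given, `per_cyst.csv`,
#'   `summary.csv` and `run_log.txt` are written there.
#' @return list with `per_cyst` (data.frame), `summary` (a
#'   [aggregate_replicates()] result, or `NULL` for a one-arm run) and `log`
#'   (character vector of stage messages).
#' @export
run_pipeline <- function(params = simulation_params(),
                         n_cysts = 10L,
                         n_replicates = 3L,
                         conditions = c(vehicle = FALSE, treated = TRUE),
                         det_cfg = detection_config(),
                         fyve_det_cfg = detection_config(
                           enhancement_scales = c(0.8, 2.8)),
                         quant_cfg = quant_config(),
                         bg_cfg = detection_config(growth_fraction = 0.6),
                         bg_min_volume = 0.05,
                         seed = 1L,
                         out_dir = NULL) {
  stopifnot(is.logical(conditions), !is.null(names(conditions)))
  validate_simulation_params(params)
  t0 <- Sys.time()
  log <- character(0)
  note <- function(...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   paste0(...))
    log <<- c(log, msg)
  }
  note("pipeline start: ", n_cysts, " cyst(s) x ",
       length(conditions), " condition(s), ", n_replicates,
       " replicate(s), seed ", seed)

  set.seed(seed)
  n_total <- n_cysts * length(conditions)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, 2L * max(n_total, 1L))

  rows <- list()
  k <- 0L
  for (ci in seq_along(conditions)) {
    cond <- names(conditions)[ci]
    p_cond <- if (conditions[[ci]]) apply_knockdown(params) else params
    for (i in seq_len(n_cysts)) {
      k <- k + 1L
      stage <- "simulate"
      row <- tryCatch({
        p_i <- p_cond
        p_i$seed <- sim_seeds[2L * k - 1L]
        sim <- simulate_cyst_volume(p_i)
        p_ctrl <- p_cond
        p_ctrl$seed <- sim_seeds[2L * k]
        ctrl <- simulate_control_volume(p_ctrl)
        stage <- "background"
        bg <- estimate_background(ctrl, bg_cfg, min_volume = bg_min_volume)
        v <- subtract_background(sim$volume, bg)
        if (!is.na(v$skew_angle)) {
          stage <- "deskew"
          v <- deskew_volume(v)
        }
        stage <- "cyst segmentation"
        mask <- segment_cyst(v)
        stage <- "puncta detection"
        cfg_map <- list(FYVE = fyve_det_cfg, .default = det_cfg)
        segs <- detect_puncta(v, cfg_map, mask = mask,
                              scale_stack = sim$volume)
        stage <- "quantification"
        segs <- filter_by_volume(segs, quant_cfg)
        res <- cooccurrence_ratios(segs, quant_cfg, cyst_id = k,
                                   condition = cond)
        out <- as.data.frame(res)
        out$replicate <- ((i - 1L) %% n_replicates) + 1L
        out$seed <- p_i$seed
        out$cyst_volume <- mean(mask$cyst_volume)
        out$background_mean <- mean(bg$per_timepoint_mean)
        out
      }, error = function(e) {
        stop("pipeline failed at stage '", stage, "' for condition '", cond,
             "', cyst ", i, ": ", conditionMessage(e), call. = FALSE)
      })
      rows[[k]] <- row
      note("cyst ", k, " (", cond, "): ", row$count_ATG9, "/",
           row$count_ATG8, "/", row$count_FYVE, " puncta")
    }
  }

  per_cyst <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cyst_id = integer(0), condition = character(0),
               replicate = integer(0))
  summary <- NULL
  if (length(conditions) == 2 && nrow(per_cyst) > 0 && n_replicates >= 2) {
    summary <- aggregate_replicates(per_cyst, conditions = names(conditions))
    note("aggregated ", nrow(summary), " metric(s) over ", n_replicates,
         " replicate(s)")
  }
  note("pipeline done")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_cyst, file.path(out_dir, "per_cyst.csv"),
              row.names = FALSE)
    if (!is.null(summary)) {
      write.csv(as.data.frame(unclass(summary)),
                file.path(out_dir, "summary.csv"), row.names = FALSE)
    }
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(per_cyst = per_cyst, summary = summary, log = log)
}
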