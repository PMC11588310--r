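#' Detection parameters for particle enhancement and blob segmentation
#'
#' @param enhancement_scales numeric vector of blob diameters in um at which
#'   the band-pass enhancer responds maximally. Default 0.8 um, matching
#'   sub-micron autophagic puncta.
#' @param response_threshold seed threshold for local maxima of the enhanced
#'   response. With `threshold_type = "relative"` (default) it is a multiple
#'   of the robust scale (MAD) of the enhanced response over the region under
#'   consideration; with `"absolute"` it is used as-is.
#' @param threshold_type `"relative"` or `"absolute"`.
#' @param min_separation minimum physical distance (um) between accepted
#'   seeds; of two seeds closer than this, the one with the stronger response
#'   wins.
#' @param growth_fraction each seed grows into the connected region of voxels
#'   whose enhanced response is at least this fraction of the seed's peak
#'   response; must be in (0, 1).
#' @param restrict_to_cyst if `TRUE` and a cyst mask is supplied to
#'   [segment_blobs()], both the robust-scale estimate and the final segments
#'   are restricted to the mask.
#' @return An object of class `DetectionConfig`.
#' @export
detection_config <- function(enhancement_scales = 0.8,
                             response_threshold = 8,
                             threshold_type = c("relative", "absolute"),
                             min_separation = 0.5,
                             growth_fraction = 0.3,
                             restrict_to_cyst = TRUE) {
  threshold_type <- match.arg(threshold_type)
  if (any(enhancement_scales <= 0)) stop("enhancement scales must be > 0")
  if (growth_fraction <= 0 || growth_fraction >= 1) {
    stop("growth_fraction must be in (0, 1)")
  }
  if (min_separation < 0) stop("min_separation must be >= 0")
  if (response_threshold < 0) stop("response_threshold must be >= 0")
  structure(
    list(
      enhancement_scales = as.numeric(enhancement_scales),
      response_threshold = response_threshold,
      threshold_type = threshold_type,
      min_separation = min_separation,
      growth_fraction = growth_fraction,
      restrict_to_cyst = isTRUE(restrict_to_cyst)
    ),
    class = "DetectionConfig"
  )
}

# Inner/outer Gaussian sigmas of the center-surround operator for a blob
# diameter `scale` (um). The inner sigma matches a blob of that diameter;
# the surround is twice as wide.
dog_sigmas <- function(scale) {
  c(inner = scale / 4, outer = scale / 2)
}

#' Separable anisotropic 3D Gaussian blur in physical units
#'
#' Blurs a `(z, y, x)` array with an axis-separable Gaussian whose standard
#' deviation is given in micrometers, converted per axis with the voxel
#' spacing, so anisotropic voxels are handled correctly. Borders are
#' renormalized (truncated kernel weights are rescaled to sum to one), so a
#' constant image is exactly preserved.
#'
#' @param vol 3D numeric array `(z, y, x)`.
#' @param spacing voxel spacing in um `(dz, dy, dx)`.
#' @param sigma Gaussian sd in um; scalar (isotropic) or length 3 per axis.
#' @return blurred array of the same shape.
#' @export
gauss_blur_3d <- function(vol, spacing, sigma) {
  d <- dim(vol)
  stopifnot(length(d) == 3, length(spacing) == 3)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  out <- vol
  for (a in 1:3) {
    if (sigma[a] <= 0) next
    s_vox <- sigma[a] / spacing[a]
    r <- max(1L, as.integer(ceiling(3.5 * s_vox)))
    k <- dnorm(seq(-r, r), sd = s_vox)
    k <- k / sum(k)
    out <- conv_axis_3d(out, as.integer(d), a - 1L, k)
  }
  dim(out) <- d
  out
}

#' Band-pass particle enhancement
#'
#' Center-surround (difference-of-Gaussians) filter that suppresses smooth
#' local background and enhances blob-like structures at the configured
#' physical scales. The response is near zero on constant or linearly varying
#' intensity, and maximal at the center of blobs whose diameter matches an
#' enhancement scale. With several scales, the voxelwise maximum response is
#' returned.
#'
#' @param channel_volume non-negative 3D array `(z, y, x)`.
#' @param spacing voxel spacing in um `(dz, dy, dx)`.
#' @param cfg a [detection_config()].
#' @return 3D array of enhanced responses (may contain negative values in the
#'   surround of bright structures).
#' @export
enhance_particles <- function(channel_volume, spacing, cfg = detection_config()) {
  d <- dim(channel_volume)
  stopifnot(length(d) == 3)
  if (min(channel_volume) < 0) stop("input intensities must be non-negative")
  if (any(vapply(cfg$enhancement_scales, function(s) any(s < spacing), TRUE))) {
    stop("enhancement scale smaller than one voxel along some axis")
  }
  resp <- NULL
  for (sc in cfg$enhancement_scales) {
    sg <- dog_sigmas(sc)
    r <- gauss_blur_3d(channel_volume, spacing, sg[["inner"]]) -
      gauss_blur_3d(channel_volume, spacing, sg[["outer"]])
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  dim(resp) <- d
  resp
}

#' Segment blob-like puncta from an enhanced response
#'
#' Detects local maxima of the enhanced response above the configured
#' threshold, suppresses maxima closer than `min_separation` (the stronger
#' response wins), grows each surviving seed into the 6-connected region of
#' voxels with response at least `growth_fraction` of the seed's peak (voxels
#' contested between seeds go to the physically nearer peak, ties to the
#' lower seed id), optionally intersects segments with a cyst mask, and
#' returns per-segment statistics measured on the raw volume.
#'
#' @param enhanced 3D enhanced response from [enhance_particles()].
#' @param raw 3D raw intensity volume of the same shape; segment statistics
#'   (mean intensity, and the intensities background estimation averages) are
#'   taken from here.
#' @param spacing voxel spacing in um `(dz, dy, dx)`.
#' @param cfg a [detection_config()].
#' @param mask optional logical 3D array restricting detection to a cyst.
#' @param scale_reference optional 3D enhanced response used only to compute
#'   the relative threshold's robust scale. After clamped background
#'   subtraction most of a sparse channel is censored at zero and its own
#'   response MAD underestimates the noise floor, so the scale should be
#'   taken from the enhanced uncorrected acquisition.
#' @param channel,timepoint labels stamped onto the returned segments.
#' @return A `data.frame` with one row per segment: `id`, `channel`,
#'   `timepoint`, `voxel_count`, `volume` (um^3), centroid `cz`, `cy`, `cx`
#'   (um), `mean_raw_intensity`, `peak_response`, bounding box columns
#'   (0-based voxel index ranges), and a `voxels` list column of 1-based
#'   linear voxel indices. Grid shape and spacing are attached as attributes
#'   `grid_dim` and `spacing`. An empty result is valid.
#' @export
segment_blobs <- function(enhanced, raw, spacing, cfg = detection_config(),
                          mask = NULL, scale_reference = NULL,
                          channel = NA_character_, timepoint = 1L) {
  d <- dim(enhanced)
  stopifnot(length(d) == 3)
  if (!identical(dim(raw), d)) stop("'enhanced' and 'raw' must share shape")
  if (!is.null(mask) && !identical(dim(mask), d)) {
    stop("'mask' must share the volume shape")
  }
  use_mask <- !is.null(mask) && cfg$restrict_to_cyst

  thr <- cfg$response_threshold
  if (cfg$threshold_type == "relative") {
    ref <- if (is.null(scale_reference)) enhanced else scale_reference
    region <- if (use_mask) ref[mask] else ref
    thr <- cfg$response_threshold * mad(region, center = median(region))
  }

  seeds <- local_maxima_3d(enhanced, as.integer(d), thr,
                           if (use_mask) mask else logical(0))
  segs <- empty_segments(d, spacing)
  if (length(seeds) == 0) {
    segs$channel <- as.character(segs$channel)
    return(stamp_segments(segs, channel, timepoint))
  }

  ord <- order(enhanced[seeds], decreasing = TRUE)
  seeds <- seeds[ord]
  if (cfg$min_separation > 0 && length(seeds) > 1) {
    seeds <- suppress_close_seeds(seeds, d, spacing, cfg$min_separation)
  }

  labels <- grow_blobs_3d(enhanced, as.integer(d), seeds,
                          cfg$growth_fraction, spacing)
  if (use_mask) labels[!mask] <- 0L

  idx <- which(labels > 0L)
  if (length(idx) == 0) return(stamp_segments(segs, channel, timepoint))
  by_lab <- split(idx, labels[idx])

  vv <- voxel_volume(spacing)
  rows <- lapply(seq_along(by_lab), function(k) {
    vox <- by_lab[[k]]
    co <- voxel_coords(vox, d)
    seed_i <- seeds[as.integer(names(by_lab)[k])]
    data.frame(
      id = k,
      voxel_count = length(vox),
      volume = length(vox) * vv,
      cz = mean(co[, 1]) * spacing[1],
      cy = mean(co[, 2]) * spacing[2],
      cx = mean(co[, 3]) * spacing[3],
      mean_raw_intensity = mean(raw[vox]),
      peak_response = enhanced[seed_i],
      bb_z0 = min(co[, 1]), bb_z1 = max(co[, 1]),
      bb_y0 = min(co[, 2]), bb_y1 = max(co[, 2]),
      bb_x0 = min(co[, 3]), bb_x1 = max(co[, 3])
    )
  })
  segs <- do.call(rbind, rows)
  segs$voxels <- unname(by_lab)
  attr(segs, "grid_dim") <- d
  attr(segs, "spacing") <- setNames(as.numeric(spacing), c("dz", "dy", "dx"))
  stamp_segments(segs, channel, timepoint)
}

suppress_close_seeds <- function(seeds, d, spacing, min_sep) {
  co <- voxel_coords(seeds, d)
  co <- sweep(co, 2, spacing, `*`)
  keep <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    ok <- TRUE
    if (any(keep)) {
      prev <- co[keep, , drop = FALSE]
      dist2 <- (prev[, 1] - co[i, 1])^2 + (prev[, 2] - co[i, 2])^2 +
        (prev[, 3] - co[i, 3])^2
      ok <- all(dist2 >= min_sep^2)
    }
    keep[i] <- ok
  }
  seeds[keep]
}

# 0-based (z, y, x) voxel coordinates from 1-based linear indices.
voxel_coords <- function(idx, d) {
  i0 <- idx - 1L
  z <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  x <- i0 %/% (d[1] * d[2])
  cbind(z = z, y = y, x = x)
}

empty_segments <- function(d, spacing) {
  segs <- data.frame(
    id = integer(0), voxel_count = integer(0), volume = numeric(0),
    cz = numeric(0), cy = numeric(0), cx = numeric(0),
    mean_raw_intensity = numeric(0), peak_response = numeric(0),
    bb_z0 = integer(0), bb_z1 = integer(0), bb_y0 = integer(0),
    bb_y1 = integer(0), bb_x0 = integer(0), bb_x1 = integer(0)
  )
  segs$voxels <- list()
  attr(segs, "grid_dim") <- d
  attr(segs, "spacing") <- setNames(as.numeric(spacing), c("dz", "dy", "dx"))
  segs
}

stamp_segments <- function(segs, channel, timepoint) {
  segs$channel <- rep(as.character(channel), nrow(segs))
  segs$timepoint <- rep(as.integer(timepoint), nrow(segs))
  front <- c("id", "channel", "timepoint")
  segs[, c(front, setdiff(names(segs), front))]
}

#' Segment the cyst body from a multi-channel volume
#'
#' Intensity-based cyst segmentation: channels are summed, smoothed at a
#' coarse scale, thresholded with a global-histogram (Otsu) criterion, the
#' largest 6-connected component is kept, interior holes are filled, and the
#' mask is closed morphologically. One connected foreground component is
#' produced per timepoint.
#'
#' @param v a [VolumeStack].
#' @param smooth_sigma coarse smoothing scale in um (default 0.5).
#' @return An object of class `CystMask`: a list with the logical mask array
#'   `(z, y, x, timepoint)`, per-timepoint `cyst_volume` in um^3, and the
#'   voxel `spacing`.
#' @export
segment_cyst <- function(v, smooth_sigma = 0.5) {
  stopifnot(inherits(v, "VolumeStack"))
  d <- dim(v$data)[1:3]
  nt <- n_timepoints(v)
  mask <- array(FALSE, c(d, nt))
  vols <- numeric(nt)
  for (t in seq_len(nt)) {
    s <- array(0, d)
    for (ci in seq_along(v$channels)) s <- s + get_channel(v, ci, t)
    sm <- gauss_blur_3d(s, v$spacing, smooth_sigma)
    thr <- cyst_threshold(sm)
    fg <- sm > thr
    if (!any(fg)) abort_no_cyst(t)
    lab <- label_components_3d(fg, as.integer(d))
    tab <- tabulate(lab[lab > 0L])
    fg <- lab == which.max(tab)
    dim(fg) <- d
    fg <- fill_holes_3d(fg, as.integer(d))
    fg <- morph_binary_3d(fg, as.integer(d), 1L, 1L)  # close: dilate ...
    fg <- morph_binary_3d(fg, as.integer(d), 2L, 1L)  # ... then erode
    fg <- fill_holes_3d(fg, as.integer(d))
    # closing can only merge, never split, so the component stays connected
    mask[, , , t] <- fg
    vols[t] <- sum(fg) * voxel_volume(v)
  }
  structure(
    list(mask = mask, cyst_volume = vols, spacing = v$spacing),
    class = "CystMask"
  )
}

#' @export
print.CystMask <- function(x, ...) {
  cat("CystMask:", paste(dim(x$mask)[1:3], collapse = " x "),
      "voxels,", dim(x$mask)[4], "timepoint(s); volume (um^3):",
      paste(signif(x$cyst_volume, 4), collapse = ", "), "\n")
  invisible(x)
}

cyst_mask_at <- function(mask, t) {
  if (is.null(mask)) return(NULL)
  if (inherits(mask, "CystMask")) {
    m <- mask$mask[, , , min(t, dim(mask$mask)[4])]
    dim(m) <- dim(mask$mask)[1:3]
    return(m)
  }
  mask
}

# Foreground/background threshold for the cyst body. Otsu on the
# tail-clipped histogram separates background from cyst voxels, but the
# foreground class mixes the diffuse rim with much brighter puncta and
# organelles, so the cut is placed a fixed fraction of the way from the
# background median to the foreground median - near the half-height of the
# diffuse fill step and insensitive to the bright-object tail.
cyst_threshold <- function(x, cut_fraction = 0.25) {
  hi <- stats::quantile(x, 0.99, names = FALSE)
  xc <- pmin(x, hi)
  t0 <- otsu_threshold(xc)
  m0 <- median(xc[xc <= t0])
  m1 <- median(xc[xc > t0])
  if (!is.finite(m1)) return(t0)
  m0 + cut_fraction * (m1 - m0)
}

# Global-histogram Otsu threshold (maximizes between-class variance) on the
# full 3D intensity distribution.
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[2] - rng[1] < .Machine$double.eps) {
    abort_no_cyst(NA_integer_)
  }
  h <- tabulate(pmin(nbins, 1L + as.integer((x - rng[1]) / (rng[2] - rng[1]) *
                                              nbins)), nbins)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  bcv <- (mu_t * om - mu)^2 / (om * (1 - om))
  bcv[!is.finite(bcv)] <- 0
  k <- which.max(bcv)
  rng[1] + k / nbins * (rng[2] - rng[1])
}

abort_no_cyst <- function(timepoint) {
  msg <- if (is.na(timepoint)) {
    "no cyst foreground found (empty or constant volume)"
  } else {
    paste0("no cyst foreground found at timepoint ", timepoint)
  }
  stop(structure(
    class = c("cystpuncta_no_cyst_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Detect puncta in every channel and timepoint of a volume
#'
#' Convenience wrapper running [enhance_particles()] and [segment_blobs()]
#' over the requested channels and timepoints and combining the segments into
#' one table with globally unique ids.
#'
#' @param v a [VolumeStack].
#' @param cfg a [detection_config()] applied to every channel, or a named
#'   list of configs keyed by channel label (with an optional `.default`
#'   entry). Organelle-scale channels such as FYVE typically need an extra
#'   coarse enhancement scale so the large bodies are segmented as solid
#'   objects rather than band-pass shells.
#' @param mask optional [segment_cyst()] result (or logical array) to
#'   restrict detection.
#' @param channels channel labels to process (default: all).
#' @param scale_stack optional [VolumeStack] (typically the uncorrected
#'   acquisition) whose enhanced response sets the relative threshold scale;
#'   see [segment_blobs()].
#' @return segments `data.frame` as in [segment_blobs()].
#' @export
detect_puncta <- function(v, cfg = detection_config(), mask = NULL,
                          channels = NULL, scale_stack = NULL) {
  stopifnot(inherits(v, "VolumeStack"))
  if (is.null(channels)) channels <- v$channels
  cfg_for <- function(ch) {
    if (inherits(cfg, "DetectionConfig")) return(cfg)
    if (!is.null(cfg[[ch]])) return(cfg[[ch]])
    if (!is.null(cfg[[".default"]])) return(cfg[[".default"]])
    stop("no detection config for channel '", ch, "'")
  }
  out <- NULL
  for (ch in channels) {
    ch_cfg <- cfg_for(ch)
    for (t in seq_len(n_timepoints(v))) {
      raw <- get_channel(v, ch, t)
      enh <- enhance_particles(raw, v$spacing, ch_cfg)
      sref <- NULL
      if (!is.null(scale_stack)) {
        raw_ref <- get_channel(scale_stack, ch, t)
        sref <- if (identical(raw_ref, raw)) enh else
          enhance_particles(raw_ref, v$spacing, ch_cfg)
      }
      segs <- segment_blobs(enh, raw, v$spacing, ch_cfg,
                            mask = cyst_mask_at(mask, t),
                            scale_reference = sref,
                            channel = ch, timepoint = t)
      out <- if (is.null(out)) segs else rbind_segments(out, segs)
    }
  }
  if (nrow(out) > 0) out$id <- seq_len(nrow(out))
  out
}

rbind_segments <- function(a, b) {
  at <- attributes(a)
  out <- rbind(a, b)
  attr(out, "grid_dim") <- at$grid_dim
  attr(out, "spacing") <- at$spacing
  out
}
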