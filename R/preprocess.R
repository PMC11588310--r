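#' Deskew an obliquely acquired volume into orthogonal coordinates
#'
#' Lattice light sheet stacks are acquired with the detection objective at an
#' angle to the coverslip, so successive Z planes are laterally offset. The
#' deskew is a per-slice shear along Y: slice `z` is shifted by
#' `z * dz * cos(angle) / dy` voxels, rounded to the nearest voxel in the
#' default integer-shift mode, with the Y axis padded so no data is cropped.
#' Integer shifts move intensity without rescaling it, so the total intensity
#' is conserved exactly; an interpolating (`"linear"`) mode exists but is off
#' by default.
#'
#' @param v a [VolumeStack] with `skew_angle` set.
#' @param angle acquisition angle in degrees, in (0, 90]; defaults to the
#'   volume's `skew_angle`.
#' @param method `"nearest"` (integer shifts, exact conservation) or
#'   `"linear"` (interpolating shear).
#' @return a [VolumeStack] on an orthogonal grid with `skew_angle` cleared.
#' @export
deskew_volume <- function(v, angle = v$skew_angle,
                          method = c("nearest", "linear")) {
  stopifnot(inherits(v, "VolumeStack"))
  method <- match.arg(method)
  if (is.na(v$skew_angle)) {
    warning("volume is already orthogonal; deskew is a no-op")
    return(v)
  }
  if (!is.finite(angle) || angle <= 0 || angle > 90) {
    stop("deskew angle must be in (0, 90] degrees")
  }
  d <- dim(v$data)
  nz <- d[1]; ny <- d[2]
  sp <- v$spacing
  shift_f <- (seq_len(nz) - 1) * sp["dz"] * cos(angle * pi / 180) / sp["dy"]

  if (method == "nearest") {
    shifts <- as.integer(round(shift_f))
    ny2 <- ny + max(shifts)
    out <- array(0, c(nz, ny2, d[3], d[4], d[5]))
    for (z in seq_len(nz)) {
      s <- shifts[z]
      out[z, (1 + s):(ny + s), , , ] <- v$data[z, , , , , drop = FALSE]
    }
  } else {
    ny2 <- ny + as.integer(ceiling(max(shift_f)))
    out <- array(0, c(nz, ny2, d[3], d[4], d[5]))
    for (z in seq_len(nz)) {
      s0 <- floor(shift_f[z])
      w <- shift_f[z] - s0
      sl <- v$data[z, , , , , drop = FALSE]
      out[z, (1 + s0):(ny + s0), , , ] <-
        out[z, (1 + s0):(ny + s0), , , , drop = FALSE] + (1 - w) * sl
      out[z, (2 + s0):(ny + s0 + 1), , , ] <-
        out[z, (2 + s0):(ny + s0 + 1), , , , drop = FALSE] + w * sl
    }
  }
  VolumeStack(out, sp, channels = v$channels, skew_angle = NA_real_)
}

#' Per-timepoint background of the bleed-through-contaminated channel
#'
#' Estimates, from a matched control acquisition of a strain lacking the
#' channel-1 fluorophore, the background intensity to subtract from channel 1
#' of experimental data. Per timepoint, the control's target channel is
#' particle-enhanced and segmented exactly like experimental data — in a
#' control every detected segment is an artifact (autofluorescence, noise, or
#' a bleed-through ghost of a channel-2 punctum) — segments are filtered by
#' volume, and the mean raw (unenhanced) intensity over all retained segment
#' voxels is the timepoint's background value. If no segment survives at a
#' timepoint the estimate falls back to the mean intensity of the cyst region
#' (or of the whole volume when no cyst is found), flagged in the provenance
#' table.
#'
#' @param control a [VolumeStack] from [simulate_control_volume()] or a real
#'   control acquisition.
#' @param det_cfg a [detection_config()] for the enhancement/segmentation of
#'   the control; the default uses a tight `growth_fraction` of 0.6 so the
#'   averaged voxels sit near ghost peaks.
#' @param channel label of the contaminated channel (default: first channel).
#' @param min_volume volume filter (um^3) applied to control segments before
#'   averaging. Smaller than the analysis filter by default so that even
#'   compact ghost cores contribute.
#' @return A `BackgroundModel`: list with `channel`, `per_timepoint_mean`,
#'   and a `provenance` data.frame (`timepoint`, `n_segments`, `fallback`).
#' @export
estimate_background <- function(control,
                                det_cfg = detection_config(growth_fraction = 0.6),
                                channel = NULL,
                                min_volume = 0.05) {
  stopifnot(inherits(control, "VolumeStack"))
  if (is.null(channel)) channel <- control$channels[1]
  channel_index(control, channel)  # validates presence
  nt <- n_timepoints(control)
  bg <- numeric(nt)
  nseg <- integer(nt)
  fallback <- logical(nt)
  cyst <- NULL
  cyst_tried <- FALSE
  for (t in seq_len(nt)) {
    raw <- get_channel(control, channel, t)
    enh <- enhance_particles(raw, control$spacing, det_cfg)
    segs <- segment_blobs(enh, raw, control$spacing, det_cfg,
                          channel = channel, timepoint = t)
    segs <- segs[segs$volume >= min_volume - 1e-12, , drop = FALSE]
    if (nrow(segs) > 0) {
      vox <- unique(unlist(segs$voxels))
      bg[t] <- mean(raw[vox])
      nseg[t] <- nrow(segs)
    } else {
      if (!cyst_tried) {
        cyst <- tryCatch(segment_cyst(control), error = function(e) NULL)
        cyst_tried <- TRUE
      }
      bg[t] <- if (!is.null(cyst)) {
        m <- cyst_mask_at(cyst, t)
        mean(raw[m])
      } else {
        mean(raw)
      }
      fallback[t] <- TRUE
    }
  }
  structure(
    list(
      channel = channel,
      per_timepoint_mean = bg,
      provenance = data.frame(timepoint = seq_len(nt), n_segments = nseg,
                              fallback = fallback)
    ),
    class = "BackgroundModel"
  )
}

#' @export
print.BackgroundModel <- function(x, ...) {
  cat("BackgroundModel for channel", x$channel, "-",
      length(x$per_timepoint_mean), "timepoint(s)\n")
  cat("  mean background:", paste(signif(x$per_timepoint_mean, 4),
                                  collapse = ", "), "\n")
  if (any(x$provenance$fallback)) {
    cat("  fallback (no control segments) at timepoint(s):",
        paste(which(x$provenance$fallback), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subtract a per-timepoint background from one channel
#'
#' The target channel becomes `max(intensity - background[t], 0)` voxelwise;
#' other channels are untouched. The clamp at zero keeps intensities
#' non-negative for downstream detection.
#'
#' @param v a [VolumeStack].
#' @param bg a `BackgroundModel` from [estimate_background()].
#' @return a corrected [VolumeStack].
#' @export
subtract_background <- function(v, bg) {
  stopifnot(inherits(v, "VolumeStack"), inherits(bg, "BackgroundModel"))
  ci <- channel_index(v, bg$channel)
  nt <- n_timepoints(v)
  if (length(bg$per_timepoint_mean) != nt) {
    stop("background model has ", length(bg$per_timepoint_mean),
         " timepoints but the volume has ", nt)
  }
  if (any(bg$per_timepoint_mean < 0)) stop("background values must be >= 0")
  out <- v
  for (t in seq_len(nt)) {
    out$data[, , , ci, t] <- pmax(out$data[, , , ci, t] -
                                    bg$per_timepoint_mean[t], 0)
  }
  out
}
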