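#' Multi-channel, multi-timepoint 3D volume with physical voxel spacing
#'
#' A `VolumeStack` holds a non-negative intensity grid indexed
#' `[z, y, x, channel, timepoint]` together with the physical voxel spacing in
#' micrometers, ordered channel labels, and an optional acquisition skew angle
#' (degrees between the detection axis and the coverslip normal; `NA` for
#' volumes already on an orthogonal grid). Voxel centers sit at
#' `index * spacing` with 0-based indices, so the voxel at index 0 is at
#' physical coordinate 0.
#'
#' @param data numeric array. A 3D `(z, y, x)`, 4D `(z, y, x, channel)` or 5D
#'   `(z, y, x, channel, timepoint)` array of non-negative intensities; lower
#'   dimensionalities are promoted with singleton channel/time axes.
#' @param spacing numeric length-3, voxel spacing in um as `(dz, dy, dx)`.
#' @param channels character vector of unique channel labels, one per channel
#'   plane. Defaults to `c("ATG9", "ATG8", "FYVE")` truncated to the number of
#'   channels present.
#' @param skew_angle numeric scalar in degrees, or `NA` if the volume is
#'   already orthogonal.
#' @return An object of class `VolumeStack`.
#' @seealso [get_channel()], [deskew_volume()], [simulate_cyst_volume()]
#' @export
VolumeStack <- function(data, spacing,
                        channels = NULL,
                        skew_angle = NA_real_) {
  if (!is.array(data) && !is.numeric(data)) {
    stop("'data' must be a numeric array")
  }
  d <- dim(data)
  if (is.null(d) || length(d) < 3 || length(d) > 5) {
    stop("'data' must have 3 to 5 dimensions (z, y, x[, channel[, time]])")
  }
  if (length(d) == 3) dim(data) <- c(d, 1L, 1L)
  if (length(d) == 4) dim(data) <- c(d, 1L)
  d <- dim(data)
  if (any(d < 1L)) stop("all axis lengths must be >= 1")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 strictly positive values (dz, dy, dx) in um")
  }
  if (is.null(channels)) {
    channels <- c("ATG9", "ATG8", "FYVE")[seq_len(d[4])]
    if (anyNA(channels)) channels <- paste0("ch", seq_len(d[4]))
  }
  if (length(channels) != d[4]) {
    stop("'channels' must name each of the ", d[4], " channel planes")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (min(data) < 0) stop("intensities must be non-negative")
  if (!is.na(skew_angle) && (skew_angle <= 0 || skew_angle > 90)) {
    stop("'skew_angle' must be in (0, 90] degrees or NA")
  }
  structure(
    list(
      data = data,
      spacing = setNames(as.numeric(spacing), c("dz", "dy", "dx")),
      channels = as.character(channels),
      skew_angle = skew_angle
    ),
    class = "VolumeStack"
  )
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim(x$data)
  cat("VolumeStack: ", d[1], " x ", d[2], " x ", d[3],
      " voxels (z,y,x), ", d[4], " channel(s) [",
      paste(x$channels, collapse = ", "), "], ", d[5], " timepoint(s)\n",
      sep = "")
  cat("  spacing (um):", paste(signif(x$spacing, 4), collapse = " x "),
      " skew:", ifelse(is.na(x$skew_angle), "none",
                       paste0(x$skew_angle, " deg")), "\n")
  invisible(x)
}

#' Extract one channel/timepoint as a 3D array
#'
#' @param v a [VolumeStack].
#' @param channel channel label or index.
#' @param timepoint timepoint index (1-based).
#' @return 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(v, channel, timepoint = 1L) {
  stopifnot(inherits(v, "VolumeStack"))
  ci <- channel_index(v, channel)
  nt <- dim(v$data)[5]
  if (timepoint < 1 || timepoint > nt) stop("timepoint out of range")
  arr <- v$data[, , , ci, timepoint]
  dim(arr) <- dim(v$data)[1:3]
  arr
}

#' Number of timepoints in a VolumeStack
#' @param v a [VolumeStack].
#' @return integer count.
#' @export
n_timepoints <- function(v) {
  stopifnot(inherits(v, "VolumeStack"))
  dim(v$data)[5]
}

channel_index <- function(v, channel) {
  if (is.character(channel)) {
    ci <- match(channel, v$channels)
    if (is.na(ci)) stop("channel '", channel, "' not present")
  } else {
    ci <- as.integer(channel)
    if (ci < 1 || ci > length(v$channels)) stop("channel index out of range")
  }
  ci
}

#' Physical volume of one voxel
#' @param x a [VolumeStack] or a length-3 spacing vector in um.
#' @return voxel volume in um^3.
#' @export
voxel_volume <- function(x) {
  sp <- if (inherits(x, "VolumeStack")) x$spacing else x
  stopifnot(length(sp) == 3, all(sp > 0))
  prod(sp)
}

set_channel <- function(v, channel, timepoint, arr) {
  ci <- channel_index(v, channel)
  v$data[, , , ci, timepoint] <- arr
  v
}
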