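#' Write a VolumeStack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered timepoint-major, then channel, then Z. Intensities are
#' scaled into `[0, 1]` by a factor recorded in the sidecar (TIFF stores
#' normalized 32-bit samples), and the sidecar (`<prefix>.json`) carries the
#' grid shape, voxel spacing, channel labels, skew angle, and page order, so
#' [read_volume_stack()] restores the stack exactly up to float precision.
#'
#' @param v a [VolumeStack].
#' @param prefix output path prefix; `<prefix>.tif` and `<prefix>.json` are
#'   written.
#' @return the prefix, invisibly.
#' @export
write_volume_stack <- function(v, prefix) {
  stopifnot(inherits(v, "VolumeStack"))
  d <- dim(v$data)
  scale <- max(1, max(v$data))
  pages <- vector("list", d[5] * d[4] * d[1])
  k <- 0L
  for (t in seq_len(d[5])) {
    for (c in seq_len(d[4])) {
      for (z in seq_len(d[1])) {
        k <- k + 1L
        pg <- v$data[z, , , c, t] / scale
        dim(pg) <- d[2:3]
        pages[[k]] <- pg
      }
    }
  }
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 32L,
                  compression = "LZW")
  meta <- list(
    grid_shape = d[1:3], n_channels = d[4], n_timepoints = d[5],
    spacing_um = as.numeric(v$spacing), channels = v$channels,
    intensity_scale = scale, page_order = "t,c,z"
  )
  if (!is.na(v$skew_angle)) meta$skew_angle <- v$skew_angle
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a VolumeStack written by [write_volume_stack()]
#' @param prefix path prefix used at write time.
#' @return a [VolumeStack].
#' @export
read_volume_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  d <- as.integer(meta$grid_shape)
  nc <- as.integer(meta$n_channels)
  nt <- as.integer(meta$n_timepoints)
  arr <- array(0, c(d, nc, nt))
  k <- 0L
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      for (z in seq_len(d[1])) {
        k <- k + 1L
        arr[z, , , c, t] <- pages[[k]] * meta$intensity_scale
      }
    }
  }
  sa <- meta$skew_angle
  VolumeStack(arr, meta$spacing_um, channels = meta$channels,
              skew_angle = if (is.null(sa) || length(sa) == 0) NA_real_ else
                as.numeric(sa))
}

#' Write synthetic ground truth as CSV plus JSON sidecar
#'
#' One punctum per CSV row (channel, center, radius, partner identity); the
#' sidecar records the realized parameters: background level, bleed
#' coefficient, realized co-occurrence fractions, FYVE bodies and the
#' generator seed.
#'
#' @param truth a `SyntheticGroundTruth` from [simulate_cyst_volume()].
#' @param prefix output path prefix; `<prefix>_puncta.csv` and
#'   `<prefix>_params.json` are written.
#' @return the prefix, invisibly.
#' @export
write_ground_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "SyntheticGroundTruth"))
  write.csv(truth$puncta, paste0(prefix, "_puncta.csv"), row.names = FALSE)
  meta <- list(
    background_level = truth$background_level,
    bleed_coefficient = truth$bleed_coefficient,
    realized_fractions = as.list(truth$realized_fractions),
    fyve = truth$fyve,
    seed = truth$params$seed,
    voxel_spacing_um = as.numeric(truth$params$voxel_spacing)
  )
  jsonlite::write_json(meta, paste0(prefix, "_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Export a segments table as CSV
#'
#' Writes one row per segment (ids, channel, timepoint, voxel count, volume,
#' centroid, mean intensity) without the voxel-membership list column.
#'
#' @param segments a segments `data.frame`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  cols <- setdiff(names(segments), "voxels")
  write.csv(segments[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
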