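sp <- c(0.2, 0.1, 0.1)

# Analytic Gaussian blob rendered directly on the voxel grid (amplitude 1).
gauss_blob <- function(d, spacing, center_um, sigma_um, amp = 1) {
  z <- ((seq_len(d[1]) - 1) * spacing[1] - center_um[1])^2 / (2 * sigma_um^2)
  y <- ((seq_len(d[2]) - 1) * spacing[2] - center_um[2])^2 / (2 * sigma_um^2)
  x <- ((seq_len(d[3]) - 1) * spacing[3] - center_um[3])^2 / (2 * sigma_um^2)
  amp * exp(-outer(outer(z, y, `+`), x, `+`))
}

test_that("particle enhancement suppresses constants and linear ramps", {
  d <- c(20L, 40L, 40L)
  cfg <- detection_config()
  flat <- array(100, d)
  expect_lt(max(abs(enhance_particles(flat, sp, cfg))), 1e-6 * 100)

  blob <- 50 * gauss_blob(d, sp, c(2, 2, 2), 0.2)
  ramp <- outer(rep(1, d[1]), outer(seq_len(d[2]), rep(1, d[3])))  # linear in y
  r_blob <- enhance_particles(blob, sp, cfg)
  r_both <- enhance_particles(blob + 0.5 * ramp, sp, cfg)
  peak1 <- arrayInd(which.max(r_blob), d)
  peak2 <- arrayInd(which.max(r_both), d)
  truth <- c(2, 2, 2) / sp + 1
  expect_true(all(abs(peak1 - truth) <= 1))
  expect_true(all(abs(peak2 - peak1) <= 1))
})

test_that("enhancement rejects scales below the voxel size", {
  cfg <- detection_config(enhancement_scales = 0.15)  # < dz = 0.2
  expect_error(enhance_particles(array(1, c(8, 8, 8)), sp, cfg), "scale")
})

test_that("well-separated blobs give one segment each with accurate centroids", {
  d <- c(24L, 64L, 64L)
  c1 <- c(2.0, 2.0, 2.0); c2 <- c(2.6, 4.4, 4.4)  # ~3.4 um apart
  vol <- 100 * gauss_blob(d, sp, c1, 0.2) + 100 * gauss_blob(d, sp, c2, 0.2)
  cfg <- detection_config()
  enh <- enhance_particles(vol, sp, cfg)
  segs <- segment_blobs(enh, vol, sp, cfg)
  expect_identical(nrow(segs), 2L)
  cent <- segs[order(segs$cz), c("cz", "cy", "cx")]
  expect_true(all(abs(as.numeric(cent[1, ]) - c1) <= sp))
  expect_true(all(abs(as.numeric(cent[2, ]) - c2) <= sp))

  # min_separation larger than the blob distance suppresses the weaker seed
  cfg_wide <- detection_config(min_separation = 5)
  segs1 <- segment_blobs(enh, vol, sp, cfg_wide)
  expect_identical(nrow(segs1), 1L)
})

test_that("an all-zero volume yields an empty segment table", {
  z <- array(0, c(10, 12, 12))
  cfg <- detection_config()
  segs <- segment_blobs(enhance_particles(z, sp, cfg), z, sp, cfg)
  expect_identical(nrow(segs), 0L)
})

test_that("detection is intensity-scale equivariant under a relative threshold", {
  set.seed(9)
  d <- c(20L, 48L, 48L)
  vol <- 80 * gauss_blob(d, sp, c(1.8, 2.2, 2.2), 0.2) +
    80 * gauss_blob(d, sp, c(2.2, 3.4, 1.6), 0.25) +
    array(abs(rnorm(prod(d), 5, 1)), d)
  cfg <- detection_config()
  get_sets <- function(v) {
    enh <- enhance_particles(v, sp, cfg)
    segs <- segment_blobs(enh, v, sp, cfg)
    lapply(segs$voxels, sort)
  }
  expect_identical(get_sets(vol), get_sets(vol * 7.3))
})

test_that("segment voxel sets within a channel and timepoint are pairwise disjoint", {
  p <- small_params(seed = 13L)
  sim <- simulate_cyst_volume(p)
  segs <- detect_puncta(sim$volume, channels = "ATG8")
  vox <- unlist(segs$voxels)
  expect_identical(anyDuplicated(vox), 0L)
})

test_that("noise-free well-separated puncta are counted exactly", {
  p <- small_params(poisson_gain = 0, read_noise_sd = 0, seed = 29L,
                    background_level = 0, bleed_coefficient = 0)
  sim <- simulate_cyst_volume(p)
  segs <- detect_puncta(sim$volume, channels = c("ATG9", "ATG8"))
  tr <- sim$truth$puncta
  expect_identical(sum(segs$channel == "ATG9"), sum(tr$channel == 1L))
  expect_identical(sum(segs$channel == "ATG8"), sum(tr$channel == 2L))
})

test_that("cyst segmentation recovers the synthetic ellipsoid (Dice >= 0.9)", {
  p <- small_params(seed = 37L)
  sim <- simulate_cyst_volume(p)
  cm <- segment_cyst(sim$volume)
  m <- cm$mask[, , , 1]
  tr <- sim$truth$cyst_mask
  dice <- 2 * sum(m & tr) / (sum(m) + sum(tr))
  expect_gte(dice, 0.9)
  expect_equal(cm$cyst_volume[1], sum(m) * voxel_volume(sim$volume))
  # one connected component
  lab <- cystpuncta:::label_components_3d(m, dim(tr))
  expect_identical(max(lab), 1L)
})

test_that("cyst segmentation keeps the larger of two disjoint bright bodies and errors on empty input", {
  d <- c(20L, 40L, 40L)
  arr <- array(0, d)
  arr[5:16, 4:20, 4:20] <- 50    # large body
  arr[8:12, 30:36, 30:36] <- 50  # small body
  v <- VolumeStack(array(arr, c(d, 1, 1)), sp, channels = "ATG9")
  cm <- segment_cyst(v)
  m <- cm$mask[, , , 1]
  expect_true(all(m[8:12, 31:35, 31:35] == FALSE))
  expect_true(any(m[6:15, 5:19, 5:19]))

  zero <- VolumeStack(array(0, c(8, 8, 8)), sp)
  expect_error(segment_cyst(zero), class = "cystpuncta_no_cyst_error")
})
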