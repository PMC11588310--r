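test_that("deskew shears each Z slice by z*dz*cos(angle)/dy voxels and conserves intensity", {
  d <- c(16L, 20L, 8L)
  arr <- array(0, d)
  arr[11, 6, 4] <- 5  # 0-based voxel (z = 10, y = 5, x = 3)
  v <- VolumeStack(arr, c(0.2, 0.1, 0.1), skew_angle = 60)
  out <- deskew_volume(v)
  # shift = round(10 * 0.2 * cos(60 deg) / 0.1) = 10, so y 5 -> 15
  expect_equal(out$data[11, 16, 4, 1, 1], 5)
  expect_equal(sum(out$data), sum(v$data))
  expect_true(is.na(out$skew_angle))

  set.seed(1)
  rnd <- array(runif(prod(d)), d)
  vr <- VolumeStack(rnd, c(0.25, 0.1, 0.1), skew_angle = 47)
  expect_equal(sum(deskew_volume(vr)$data), sum(rnd), tolerance = 1e-12)
  # interpolating mode spreads weight but still conserves mass
  expect_equal(sum(deskew_volume(vr, method = "linear")$data), sum(rnd),
               tolerance = 1e-9)
})

test_that("deskew at 90 degrees is the identity and bad angles are rejected", {
  arr <- array(runif(16 * 10 * 6), c(16, 10, 6))
  v <- VolumeStack(arr, c(0.2, 0.1, 0.1), skew_angle = 90)
  out <- deskew_volume(v)
  expect_equal(dim(out$data)[1:3], dim(v$data)[1:3])
  expect_equal(out$data, v$data)

  vs <- VolumeStack(arr, c(0.2, 0.1, 0.1), skew_angle = 60)
  expect_error(deskew_volume(vs, angle = 0), "0, 90")
  expect_error(deskew_volume(vs, angle = 95), "0, 90")
  vo <- VolumeStack(arr, c(0.2, 0.1, 0.1))
  expect_warning(out2 <- deskew_volume(vo), "orthogonal")
  expect_identical(out2$data, vo$data)
})

test_that("background subtraction clamps at zero and only touches the target channel", {
  arr <- array(0, c(4, 4, 4, 2, 2))
  arr[, , , 1, 1] <- 100; arr[, , , 1, 2] <- 10
  arr[, , , 2, ] <- 55
  v <- VolumeStack(arr, c(0.2, 0.1, 0.1), channels = c("ATG9", "ATG8"))
  bg <- structure(list(channel = "ATG9", per_timepoint_mean = c(30, 30),
                       provenance = data.frame(timepoint = 1:2,
                                               n_segments = 1L,
                                               fallback = FALSE)),
                  class = "BackgroundModel")
  out <- subtract_background(v, bg)
  expect_true(all(out$data[, , , 1, 1] == 70))
  expect_true(all(out$data[, , , 1, 2] == 0))   # 10 - 30 clamps to 0
  expect_identical(out$data[, , , 2, ], v$data[, , , 2, ])

  bg0 <- bg; bg0$per_timepoint_mean <- c(0, 0)
  expect_identical(subtract_background(v, bg0)$data, v$data)

  bg_bad <- bg; bg_bad$per_timepoint_mean <- 30
  expect_error(subtract_background(v, bg_bad), "timepoints")
})

test_that("subtraction is monotone: larger backgrounds never increase a voxel", {
  set.seed(2)
  arr <- array(rpois(4 * 6 * 6 * 2, 40), c(4, 6, 6, 1, 2))
  v <- VolumeStack(arr, c(0.2, 0.1, 0.1), channels = "ATG9")
  mk <- function(b) structure(
    list(channel = "ATG9", per_timepoint_mean = rep(b, 2),
         provenance = data.frame(timepoint = 1:2, n_segments = 0L,
                                 fallback = TRUE)),
    class = "BackgroundModel")
  lo <- subtract_background(v, mk(10))$data
  hi <- subtract_background(v, mk(25))$data
  expect_true(all(hi <= lo))
})

test_that("background estimation returns the constant on uniform controls and zero on empty ones", {
  arr <- array(17, c(12, 16, 16, 3, 2))
  ctrl <- VolumeStack(arr, c(0.2, 0.1, 0.1))
  bg <- estimate_background(ctrl)
  expect_equal(bg$per_timepoint_mean, c(17, 17))

  zero <- VolumeStack(array(0, c(12, 16, 16, 3, 1)), c(0.2, 0.1, 0.1))
  bgz <- estimate_background(zero)
  expect_equal(bgz$per_timepoint_mean, 0)
  expect_identical(bgz$provenance$n_segments, 0L)
  expect_true(all(bgz$provenance$fallback))
})

test_that("background recovery on synthetic controls sits in the composed background + bleed band", {
  p <- small_params(seed = 77L, background_level = 30, bleed_coefficient = 0.1)
  sim <- simulate_cyst_volume(p)  # for the stored noise-free channel-2 signal
  ctrl <- simulate_control_volume(p)
  bg <- estimate_background(ctrl)
  upper <- p$background_level +
    p$bleed_coefficient * max(sim$truth$clean_signals$ATG8) + 5
  expect_true(all(bg$per_timepoint_mean >= p$background_level - 2))
  expect_true(all(bg$per_timepoint_mean <= upper))

  # with zero bleed and zero noise the estimate is exactly the background
  p0 <- small_params(seed = 77L, bleed_coefficient = 0, poisson_gain = 0,
                     read_noise_sd = 0)
  bg0 <- estimate_background(simulate_control_volume(p0))
  expect_equal(bg0$per_timepoint_mean, p0$background_level)
})
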