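test_that("simulation is deterministic: same params and seed, identical output", {
  p <- small_params(seed = 101L)
  a <- simulate_cyst_volume(p)
  b <- simulate_cyst_volume(p)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$puncta, b$truth$puncta)
  expect_identical(a$truth$realized_fractions, b$truth$realized_fractions)
  expect_identical(apply_knockdown(p), apply_knockdown(p))
  expect_identical(simulate_control_volume(p)$data,
                   simulate_control_volume(p)$data)
})

test_that("an empty channel contains only background, bleed-through and noise", {
  p <- small_params(
    n_puncta_per_channel = c(ATG9 = 0L, ATG8 = 5L, FYVE = 1L),
    cooccurrence_fractions = c("ATG9>ATG8" = 0, "ATG9>FYVE" = 0,
                               "ATG8>FYVE" = 0),
    poisson_gain = 0, read_noise_sd = 0, bleed_coefficient = 0,
    seed = 5L
  )
  sim <- simulate_cyst_volume(p)
  expect_identical(sum(sim$truth$puncta$channel == 1L), 0L)
  ch1 <- get_channel(sim$volume, "ATG9")
  expect_true(all(ch1 == p$background_level))
})

test_that("noise-free channel 1 equals background + bleed x channel-2 signal + own signal", {
  p <- small_params(poisson_gain = 0, read_noise_sd = 0,
                    bleed_coefficient = 0.1, seed = 17L)
  sim <- simulate_cyst_volume(p)
  composed <- sim$truth$clean_signals$ATG9 + p$background_level +
    p$bleed_coefficient * sim$truth$clean_signals$ATG8
  expect_equal(get_channel(sim$volume, "ATG9"), composed, tolerance = 1e-12)
})

test_that("forced co-occurrence places every query punctum inside a target object", {
  p <- simulation_params(
    grid_shape = c(28L, 64L, 64L), cyst_radii = c(2.2, 2.8, 2.8),
    n_timepoints = 1L,
    n_puncta_per_channel = c(ATG9 = 6L, ATG8 = 4L, FYVE = 2L),
    cooccurrence_fractions = c("ATG9>ATG8" = 0, "ATG9>FYVE" = 1.0,
                               "ATG8>FYVE" = 0),
    n_fyve_objects = 2L, fyve_object_radius = 1.2, coloc_offset = 0,
    seed = 23L
  )
  sim <- simulate_cyst_volume(p)
  tr <- sim$truth
  q <- tr$puncta[tr$puncta$channel == 1L, ]
  expect_identical(nrow(q), 6L)
  inside <- vapply(seq_len(nrow(q)), function(i) {
    d2 <- (tr$fyve$cz - q$cz[i])^2 + (tr$fyve$cy - q$cy[i])^2 +
      (tr$fyve$cx - q$cx[i])^2
    any(d2 <= tr$fyve$radius^2)
  }, TRUE)
  expect_true(all(inside))
  expect_equal(unname(tr$realized_fractions["ATG9>FYVE"]), 1.0)
})

test_that("realized fractions match an independent center-in-object recount", {
  p <- small_params(
    n_puncta_per_channel = c(ATG9 = 6L, ATG8 = 6L, FYVE = 4L),
    cooccurrence_fractions = c("ATG9>ATG8" = 0.5, "ATG9>FYVE" = 0.3,
                               "ATG8>FYVE" = 0.3),
    n_fyve_objects = 2L, fyve_object_radius = 1.2, seed = 31L
  )
  sim <- simulate_cyst_volume(p)
  tr <- sim$truth
  labs <- c("ATG9", "ATG8", "FYVE")
  recount <- function(qc, tc) {
    q <- tr$puncta[tr$puncta$channel == qc, ]
    tg <- tr$puncta[tr$puncta$channel == tc, ]
    centers <- as.matrix(tg[, c("cz", "cy", "cx")])
    radii <- tg$radius
    if (tc == 3L) {
      centers <- rbind(centers, as.matrix(tr$fyve[, c("cz", "cy", "cx")]))
      radii <- c(radii, tr$fyve$radius)
    }
    hits <- vapply(seq_len(nrow(q)), function(i) {
      d2 <- (centers[, 1] - q$cz[i])^2 + (centers[, 2] - q$cy[i])^2 +
        (centers[, 3] - q$cx[i])^2
      any(d2 <= radii^2)
    }, TRUE)
    mean(hits)
  }
  for (pr in list(c(1L, 2L), c(2L, 1L), c(1L, 3L), c(2L, 3L))) {
    key <- paste0(labs[pr[1]], ">", labs[pr[2]])
    expect_equal(unname(tr$realized_fractions[key]), recount(pr[1], pr[2]),
                 info = key)
  }
  # requested fractions are realized exactly as round(f * n) / n
  expect_equal(unname(tr$realized_fractions["ATG9>ATG8"]), round(0.5 * 6) / 6)
  expect_equal(unname(tr$realized_fractions["ATG9>FYVE"]), round(0.3 * 6) / 6)
})

test_that("every punctum center lies inside the cyst ellipsoid", {
  p <- small_params(seed = 47L)
  sim <- simulate_cyst_volume(p)
  center <- (p$grid_shape - 1) / 2 * p$voxel_spacing
  q <- sim$truth$puncta
  r2 <- ((q$cz - center[1]) / p$cyst_radii[1])^2 +
    ((q$cy - center[2]) / p$cyst_radii[2])^2 +
    ((q$cx - center[3]) / p$cyst_radii[3])^2
  expect_true(all(r2 <= 1))
})

test_that("control volumes share channels 2-3 with the experimental volume and drop channel-1 signal", {
  p <- small_params(seed = 61L, bleed_coefficient = 0.1)
  sim <- simulate_cyst_volume(p)
  ctrl <- simulate_control_volume(p)
  expect_identical(get_channel(ctrl, "ATG8"), get_channel(sim$volume, "ATG8"))
  expect_identical(get_channel(ctrl, "FYVE"), get_channel(sim$volume, "FYVE"))

  p0 <- small_params(seed = 61L, bleed_coefficient = 0,
                     poisson_gain = 0, read_noise_sd = 0)
  c0 <- simulate_control_volume(p0)
  expect_true(all(get_channel(c0, "ATG9") == p0$background_level))

  p1 <- small_params(seed = 61L, bleed_coefficient = 0.1,
                     poisson_gain = 0, read_noise_sd = 0)
  s1 <- simulate_cyst_volume(p1)
  c1 <- simulate_control_volume(p1)
  expect_equal(get_channel(c1, "ATG9"),
               p1$background_level +
                 0.1 * s1$truth$clean_signals$ATG8, tolerance = 1e-12)
})

test_that("apply_knockdown scales count, radius and flux fractions and is identity at 1", {
  p <- small_params(n_puncta_per_channel = c(ATG9 = 20L, ATG8 = 5L, FYVE = 4L),
                    punctum_radius_mean = 0.4,
                    knockdown_factor_count = 0.3,
                    knockdown_factor_radius = 0.7,
                    knockdown_factor_flux = 0.5)
  kd <- apply_knockdown(p)
  expect_identical(unname(kd$n_puncta_per_channel[1]), 6L)
  expect_equal(kd$punctum_radius_mean, 0.28)
  expect_equal(unname(kd$cooccurrence_fractions["ATG9>FYVE"]),
               unname(p$cooccurrence_fractions["ATG9>FYVE"]) * 0.5)
  expect_equal(unname(kd$cooccurrence_fractions["ATG8>FYVE"]),
               unname(p$cooccurrence_fractions["ATG8>FYVE"]) * 0.5)
  expect_identical(unname(kd$n_puncta_per_channel[2:3]),
                   unname(p$n_puncta_per_channel[2:3]))

  p1 <- small_params(knockdown_factor_count = 1, knockdown_factor_radius = 1,
                     knockdown_factor_flux = 1)
  expect_identical(apply_knockdown(p1), p1)

  expect_error(small_params(knockdown_factor_count = 0), "0, 1")
  expect_error(small_params(knockdown_factor_radius = 1.2), "0, 1")
})

test_that("impossible placement raises a placement-failure error", {
  p <- small_params(
    grid_shape = c(16L, 24L, 24L), cyst_radii = c(0.9, 0.9, 0.9),
    n_puncta_per_channel = c(ATG9 = 40L, ATG8 = 40L, FYVE = 0L),
    cooccurrence_fractions = c("ATG9>ATG8" = 0),
    max_attempts = 25L
  )
  expect_error(simulate_cyst_volume(p), class = "cystpuncta_placement_error")
})

test_that("parameter validation rejects out-of-range fields", {
  expect_error(small_params(cooccurrence_fractions = c("ATG9>ATG8" = 1.2)),
               "0, 1")
  expect_error(small_params(cyst_radii = c(5, 5, 5)), "fit")
  expect_error(small_params(voxel_spacing = c(0.2, 0, 0.1)), "spacing")
  expect_error(small_params(cooccurrence_fractions = c("FYVE>ATG9" = 0.5)),
               "named")
})
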