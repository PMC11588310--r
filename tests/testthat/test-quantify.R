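d_small <- c(16L, 20L, 20L)
sp_small <- c(0.2, 0.1, 0.1)

test_that("volume filter eliminates strictly smaller segments, at the exact printed boundary", {
  cfg <- quant_config()  # min_volume 0.2 um^3; voxel volume 0.002 um^3
  vl <- list(seq_len(99L), 100L + seq_len(100L), 300L + seq_len(250L))
  segs <- make_segments(vl, "ATG9", 1L, d_small, sp_small)
  kept <- filter_by_volume(segs, cfg)
  expect_identical(kept$voxel_count, c(100L, 250L))

  segs2 <- make_segments(list(seq_len(50L), 100L + seq_len(100L),
                              300L + seq_len(250L)), "ATG9", 1L,
                         d_small, sp_small)
  segs2$volume <- c(0.1, 0.2, 0.5)
  expect_equal(filter_by_volume(segs2, cfg)$volume, c(0.2, 0.5))

  empty <- segs[0, ]
  expect_identical(nrow(filter_by_volume(empty, cfg)), 0L)
  # order preserved
  expect_identical(kept$id, c(2L, 3L))
})

test_that("overlap_fraction counts query voxels inside the target union", {
  q <- make_segments(list(1:10), "ATG9", 1L, d_small, sp_small)
  t_same <- make_segments(list(1:10), "ATG8", 1L, d_small, sp_small)
  t_disj <- make_segments(list(101:120), "ATG8", 1L, d_small, sp_small)
  t_part <- make_segments(list(c(1:4), c(5:6, 50:60)), "ATG8", 1L,
                          d_small, sp_small)
  expect_equal(overlap_fraction(q, t_same), 1.0)
  expect_equal(overlap_fraction(q, t_disj), 0.0)
  expect_equal(overlap_fraction(q, t_part), 0.6)  # 6 of 10 voxels covered

  t_other_grid <- make_segments(list(1:10), "ATG8", 1L, c(8L, 8L, 8L),
                                sp_small)
  expect_error(overlap_fraction(q, t_other_grid), "grid")
})

test_that("co-occurrence ratios follow counts / totals with union semantics and NA for empty queries", {
  # 5 query puncta, 3 fully covered by targets -> 0.6
  qv <- lapply(0:4, function(i) (i * 30) + 1:10)
  tv <- list(c(1:10, 31:40), 61:70, 200:260)
  segs <- bind_segments(
    make_segments(qv, "ATG9", 1L, d_small, sp_small),
    make_segments(tv, "ATG8", 1L, d_small, sp_small)
  )
  res <- cooccurrence_ratios(segs, quant_config())
  pr <- res$pairs
  expect_equal(pr$ratio[pr$query == "ATG9" & pr$target == "ATG8"], 0.6)
  expect_identical(pr$numerator[pr$query == "ATG9" & pr$target == "ATG8"], 3L)
  # no FYVE segments at all: denominator > 0 gives 0, absent query gives NA
  expect_equal(pr$ratio[pr$query == "ATG9" & pr$target == "FYVE"], 0)
  expect_true(is.na(pr$ratio[pr$query == "ATG8" & pr$target == "ATG9"]) ||
                pr$ratio[pr$query == "ATG8" & pr$target == "ATG9"] >= 0)

  # identical query and target segment sets give ratio 1
  segs_id <- bind_segments(
    make_segments(qv, "ATG9", 1L, d_small, sp_small),
    make_segments(qv, "ATG8", 1L, d_small, sp_small)
  )
  res_id <- cooccurrence_ratios(segs_id, quant_config())
  expect_equal(res_id$pairs$ratio[1], 1.0)

  # empty query channel: undefined ratio, never zero
  segs_t_only <- make_segments(tv, "ATG8", 1L, d_small, sp_small)
  res_na <- cooccurrence_ratios(segs_t_only, quant_config())
  prn <- res_na$pairs
  expect_true(is.na(prn$ratio[prn$query == "ATG9" & prn$target == "ATG8"]))
  expect_identical(prn$denominator[prn$query == "ATG9" &
                                     prn$target == "ATG8"], 0L)
})

test_that("ratios match the brute-force voxel-set oracle exactly on random instances", {
  pairs <- list(c("ATG9", "ATG8"), c("ATG8", "ATG9"),
                c("ATG9", "FYVE"), c("ATG8", "FYVE"))
  cfg <- quant_config()
  n_checked <- 0L
  for (seed in 1:40) {
    inst <- random_instance(seed)
    if (is.null(inst)) next
    d <- attr(inst, "grid_dim")
    want <- oracle_ratios(inst, pairs, d, cfg$overlap_threshold)
    got <- cooccurrence_ratios(inst, cfg)$pairs
    for (i in seq_along(pairs)) {
      key <- paste(pairs[[i]], collapse = ">")
      expect_identical(got$ratio[i], want[[key]], info = paste(seed, key))
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 30L)
})

test_that("ratios are monotone in the overlap threshold and counts in the volume filter", {
  set.seed(99)
  inst <- random_instance(1234)
  ths <- c(0.5, 0.7, 0.9, 0.95)
  ratios <- sapply(ths, function(th) {
    cooccurrence_ratios(inst, quant_config(overlap_threshold = th))$pairs$ratio
  })
  for (r in seq_len(nrow(ratios))) {
    row <- ratios[r, ]
    ok <- is.na(row) | c(diff(row) <= 1e-12, TRUE)
    expect_true(all(ok | is.na(ok)))
  }
  counts <- sapply(c(0, 0.01, 0.05, 0.2), function(mv) {
    nrow(filter_by_volume(inst, quant_config(min_volume = mv)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("mean object volume averages segment volumes and is undefined on empty input", {
  segs <- make_segments(list(1:100, 101:300), "ATG9", 1L, d_small, sp_small)
  expect_equal(mean_object_volume(segs), mean(c(0.2, 0.4)))
  expect_equal(mean_object_volume(segs[1, ]), 0.2)
  expect_true(is.na(mean_object_volume(segs[0, ])))
})
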