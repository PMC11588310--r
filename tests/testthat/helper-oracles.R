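# Independent oracles and small fixtures shared across the test files.

# Small, fast simulation setting for unit tests: one small cyst, few puncta.
small_params <- function(...) {
  defaults <- list(
    grid_shape = c(28L, 64L, 64L),
    cyst_radii = c(2.2, 2.8, 2.8),
    n_timepoints = 1L,
    n_puncta_per_channel = c(ATG9 = 5L, ATG8 = 5L, FYVE = 4L),
    cooccurrence_fractions = c("ATG9>ATG8" = 0.4, "ATG9>FYVE" = 0,
                               "ATG8>FYVE" = 0),
    n_fyve_objects = 0L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

# Build a segments table by hand from voxel index lists (1-based linear
# indices into a (z, y, x) grid).
make_segments <- function(voxel_lists, channel, timepoint, d, spacing) {
  vv <- prod(spacing)
  n <- length(voxel_lists)
  segs <- data.frame(
    id = seq_len(n),
    channel = rep_len(channel, n),
    timepoint = rep_len(as.integer(timepoint), n),
    voxel_count = vapply(voxel_lists, length, 1L),
    volume = vapply(voxel_lists, length, 1L) * vv
  )
  segs$voxels <- voxel_lists
  attr(segs, "grid_dim") <- d
  attr(segs, "spacing") <- spacing
  segs
}

bind_segments <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, parts)
  out$id <- seq_len(nrow(out))
  attr(out, "grid_dim") <- attr(parts[[1]], "grid_dim")
  attr(out, "spacing") <- attr(parts[[1]], "spacing")
  out
}

# Brute-force co-occurrence oracle: enumerate voxel sets as logical arrays
# and count query puncta with > overlap_threshold of their voxels inside the
# target channel's union, per timepoint, pooled.
oracle_ratios <- function(segments, pairs, d, overlap_threshold = 0.9) {
  res <- list()
  for (pr in pairs) {
    q <- segments[segments$channel == pr[1], , drop = FALSE]
    tg <- segments[segments$channel == pr[2], , drop = FALSE]
    den <- nrow(q)
    num <- 0L
    for (t in unique(q$timepoint)) {
      tarr <- array(FALSE, d)
      for (vx in tg$voxels[tg$timepoint == t]) tarr[vx] <- TRUE
      qt <- q[q$timepoint == t, , drop = FALSE]
      for (i in seq_len(nrow(qt))) {
        frac <- mean(tarr[qt$voxels[[i]]])
        if (frac > overlap_threshold) num <- num + 1L
      }
    }
    res[[paste(pr, collapse = ">")]] <-
      if (den > 0) num / den else NA_real_
  }
  res
}

# Random segment tables on small grids for the oracle-equivalence check.
random_instance <- function(seed) {
  set.seed(seed)
  d <- sample(8:32, 3, replace = TRUE)
  spacing <- c(0.2, 0.1, 0.1)
  nt <- sample(1:2, 1)
  chans <- c("ATG9", "ATG8", "FYVE")
  parts <- list()
  for (ch in chans) {
    for (t in seq_len(nt)) {
      k <- sample(0:6, 1)
      if (k == 0) next
      vl <- lapply(seq_len(k), function(i) {
        lo <- pmax(1, c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1)) - 2)
        hi <- pmin(d, lo + sample(0:3, 3, replace = TRUE))
        g <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
        as.integer(g$z + d[1] * (g$y - 1) + d[1] * d[2] * (g$x - 1))
      })
      parts[[length(parts) + 1]] <- make_segments(vl, ch, t, d, spacing)
    }
  }
  if (length(parts) == 0) return(NULL)
  do.call(bind_segments, parts)
}

# Textbook paired t statistic and two-sided p-value.
textbook_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# Numeric quadrature of the radial convolution integral of a solid ball with
# an isotropic Gaussian, independent of the closed form in the package.
numeric_ball_profile <- function(d, radius, sigma) {
  if (d < 1e-12) d <- 1e-12
  f <- function(r) {
    r * (exp(-(d - r)^2 / (2 * sigma^2)) - exp(-(d + r)^2 / (2 * sigma^2)))
  }
  stats::integrate(f, 0, radius, rel.tol = 1e-10)$value /
    (d * sigma * sqrt(2 * pi))
}
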