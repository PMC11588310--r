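#' Parameters of the synthetic cyst-volume generator
#'
#' Defines a simulated lattice-light-sheet acquisition of one bradyzoite
#' cyst: an ellipsoidal cyst containing sub-micron puncta in three channels
#' (ATG9 at 488 nm, ATG8 at 561 nm, FYVE at 640 nm), a few large
#' digestive-organelle-like bodies in the FYVE channel, diffuse cyst fill in
#' the expressed channels, uniform autofluorescent background plus linear
#' bleed-through from the 561 channel in channel 1, anisotropic Gaussian
#' blur, and Poisson-Gaussian camera noise. The default time series matches a
#' whole-cyst volume every 20 s for 5 min (15 timepoints) with static
#' puncta.
#'
#' Co-occurrence is generated by construction: for the fraction entries named
#' `"ATG9>ATG8"`, `"ATG9>FYVE"` and `"ATG8>FYVE"`, `round(f * n_query)` query
#' puncta are placed at a partner object — at a distinct partner punctum's
#' center (plus a uniform offset within `coloc_offset`) for the punctum pair,
#' or uniformly inside a large FYVE body for the organelle pairs. All other
#' puncta keep at least `min_separation` from every other object, so they
#' never co-occur by accident. Realized fractions for all four ordered channel
#' pairs (including the emergent `"ATG8>ATG9"`) are recorded in the ground
#' truth by brute-force center-in-object testing.
#'
#' @param grid_shape voxels per `(z, y, x)` axis.
#' @param voxel_spacing um per axis `(dz, dy, dx)`. The default
#'   `(0.2, 0.1, 0.1)` gives a voxel volume of exactly 0.002 um^3, so the
#'   0.2 um^3 volume filter corresponds to 100 voxels.
#' @param n_timepoints number of acquired volumes (one per 20 s).
#' @param cyst_radii um semi-axes `(z, y, x)` of the ellipsoidal cyst.
#' @param n_puncta_per_channel named counts for `ATG9`, `ATG8`, `FYVE`.
#' @param punctum_radius_mean,punctum_radius_sd punctum radius distribution
#'   (um); radii are clamped to `[0.2, 0.58]`.
#' @param cooccurrence_fractions named fractions in `[0, 1]` for the
#'   generated ordered pairs (see Details).
#' @param coloc_offset co-localization offset radius (um) for punctum-punctum
#'   pairs; 0 places partners at identical centers.
#' @param n_fyve_objects,fyve_object_radius,fyve_intensity count, radius (um)
#'   and voxel intensity of the large FYVE-channel organelle bodies.
#' @param cyst_fill diffuse intensity added inside the cyst in the expressed
#'   channels 2 and 3 (channel 1's diffuse component is `background_level`).
#' @param background_level uniform autofluorescent background added to
#'   channel 1 (intensity units).
#' @param bleed_coefficient fraction of the noise-free channel-2 signal added
#'   to channel 1.
#' @param peak_intensity punctum intensity before blur (intensity units).
#' @param blur_sigma acquisition blur sd per axis (um).
#' @param poisson_gain Poisson noise gain; counts are drawn as
#'   `rpois(intensity * gain) / gain`. Set 0 to disable shot noise.
#' @param read_noise_sd additive Gaussian read noise sd; 0 disables.
#' @param min_separation minimum center distance (um) between non-partnered
#'   puncta.
#' @param fyve_min_separation minimum center distance (um) between
#'   same-channel puncta placed inside the same FYVE body (keeps their grown
#'   segments from truncating each other).
#' @param fyve_min_separation_cross minimum center distance (um) between
#'   puncta of different channels inside a FYVE body.
#' @param knockdown_factor_count,knockdown_factor_radius,knockdown_factor_flux
#'   multipliers in (0, 1] applied by [apply_knockdown()] to the channel-1
#'   punctum count, the global punctum radius, and the FYVE co-occurrence
#'   fractions.
#' @param drift_um optional linear drift per timepoint `(dz, dy, dx)` um;
#'   zero keeps puncta static.
#' @param max_attempts bounded retries per placed object before a
#'   placement-failure error.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   volumes and ground truth.
#' @return An object of class `SimulationParams`.
#' @seealso [simulate_cyst_volume()], [simulate_control_volume()],
#'   [apply_knockdown()]
#' @export
simulation_params <- function(grid_shape = c(40L, 112L, 112L),
                              voxel_spacing = c(0.2, 0.1, 0.1),
                              n_timepoints = 15L,
                              cyst_radii = c(3.4, 5.0, 5.0),
                              n_puncta_per_channel = c(ATG9 = 30L, ATG8 = 30L,
                                                       FYVE = 30L),
                              punctum_radius_mean = 0.45,
                              punctum_radius_sd = 0.05,
                              cooccurrence_fractions = c("ATG9>ATG8" = 0.5,
                                                         "ATG9>FYVE" = 0.3,
                                                         "ATG8>FYVE" = 0.3),
                              coloc_offset = 0,
                              n_fyve_objects = 3L,
                              fyve_object_radius = 1.4,
                              fyve_intensity = 150,
                              cyst_fill = 12,
                              background_level = 30,
                              bleed_coefficient = 0.1,
                              peak_intensity = 200,
                              blur_sigma = c(0.15, 0.15, 0.15),
                              poisson_gain = 1,
                              read_noise_sd = 3,
                              min_separation = 1.1,
                              fyve_min_separation = 0.95,
                              fyve_min_separation_cross = 0.6,
                              knockdown_factor_count = 0.3,
                              knockdown_factor_radius = 0.7,
                              knockdown_factor_flux = 0.5,
                              drift_um = c(0, 0, 0),
                              max_attempts = 2000L,
                              seed = 1L) {
  p <- structure(
    list(
      grid_shape = as.integer(grid_shape),
      voxel_spacing = setNames(as.numeric(voxel_spacing),
                               c("dz", "dy", "dx")),
      n_timepoints = as.integer(n_timepoints),
      cyst_radii = as.numeric(cyst_radii),
      n_puncta_per_channel = setNames(as.integer(n_puncta_per_channel),
                                      c("ATG9", "ATG8", "FYVE")),
      punctum_radius_mean = punctum_radius_mean,
      punctum_radius_sd = punctum_radius_sd,
      cooccurrence_fractions = cooccurrence_fractions,
      coloc_offset = coloc_offset,
      n_fyve_objects = as.integer(n_fyve_objects),
      fyve_object_radius = fyve_object_radius,
      fyve_intensity = fyve_intensity,
      cyst_fill = cyst_fill,
      background_level = background_level,
      bleed_coefficient = bleed_coefficient,
      peak_intensity = peak_intensity,
      blur_sigma = as.numeric(blur_sigma),
      poisson_gain = poisson_gain,
      read_noise_sd = read_noise_sd,
      min_separation = min_separation,
      fyve_min_separation = fyve_min_separation,
      fyve_min_separation_cross = fyve_min_separation_cross,
      knockdown_factor_count = knockdown_factor_count,
      knockdown_factor_radius = knockdown_factor_radius,
      knockdown_factor_flux = knockdown_factor_flux,
      drift_um = as.numeric(drift_um),
      max_attempts = as.integer(max_attempts),
      seed = as.integer(seed)
    ),
    class = "SimulationParams"
  )
  validate_simulation_params(p)
  p
}

validate_simulation_params <- function(p) {
  stopifnot(inherits(p, "SimulationParams") || is.list(p))
  if (length(p$grid_shape) != 3 || any(p$grid_shape < 8)) {
    stop("grid_shape must be 3 axis lengths of at least 8 voxels")
  }
  if (any(p$voxel_spacing <= 0)) stop("voxel spacing must be > 0")
  if (p$n_timepoints < 1) stop("n_timepoints must be >= 1")
  if (any(p$cyst_radii <= 0)) stop("cyst radii must be > 0")
  extent <- (p$grid_shape - 1) * p$voxel_spacing
  if (any(p$cyst_radii >= extent / 2)) {
    stop("cyst does not fit: cyst_radii must be < grid extent / 2")
  }
  if (any(p$n_puncta_per_channel < 0)) stop("puncta counts must be >= 0")
  if (p$punctum_radius_mean <= 0 || p$punctum_radius_sd < 0) {
    stop("punctum radius mean must be > 0 and sd >= 0")
  }
  f <- p$cooccurrence_fractions
  allowed <- c("ATG9>ATG8", "ATG9>FYVE", "ATG8>FYVE")
  if (is.null(names(f)) || !all(names(f) %in% allowed)) {
    stop("cooccurrence_fractions must be named among: ",
         paste(allowed, collapse = ", "))
  }
  if (any(f < 0 | f > 1)) stop("co-occurrence fractions must be in [0, 1]")
  n <- p$n_puncta_per_channel
  if (partner_count(f, "ATG9>ATG8", n[1]) + partner_count(f, "ATG9>FYVE", n[1]) > n[1]) {
    stop("requested ATG9 co-occurrence fractions sum to more than 1 punctum each")
  }
  if (p$coloc_offset < 0) stop("coloc_offset must be >= 0")
  if (p$n_fyve_objects < 0) stop("n_fyve_objects must be >= 0")
  if (p$fyve_object_radius <= 0) stop("fyve_object_radius must be > 0")
  for (fld in c("knockdown_factor_count", "knockdown_factor_radius",
                "knockdown_factor_flux")) {
    if (p[[fld]] <= 0 || p[[fld]] > 1) {
      stop(fld, " must be in (0, 1]")
    }
  }
  if (any(p$blur_sigma < 0)) stop("blur_sigma must be >= 0")
  if (p$background_level < 0 || p$bleed_coefficient < 0) {
    stop("background and bleed-through must be >= 0")
  }
  invisible(p)
}

partner_count <- function(fractions, key, n) {
  f <- if (key %in% names(fractions)) fractions[[key]] else 0
  as.integer(round(f * n))
}

#' Scale simulation parameters to emulate conditional knockdown
#'
#' Models auxin-induced depletion of the channel-1 protein: the channel-1
#' punctum count is scaled by `knockdown_factor_count` (rounded), the global
#' punctum radius by `knockdown_factor_radius`, and the autophagic-flux
#' co-occurrence fractions (`"ATG9>FYVE"` and `"ATG8>FYVE"`) by
#' `knockdown_factor_flux`. All other fields are unchanged; factors of 1
#' return the parameters identically.
#'
#' @param params a [simulation_params()] object.
#' @return modified `SimulationParams`.
#' @export
apply_knockdown <- function(params) {
  validate_simulation_params(params)
  p <- params
  p$n_puncta_per_channel[1] <-
    as.integer(round(p$n_puncta_per_channel[1] * p$knockdown_factor_count))
  p$punctum_radius_mean <- p$punctum_radius_mean * p$knockdown_factor_radius
  for (key in c("ATG9>FYVE", "ATG8>FYVE")) {
    if (key %in% names(p$cooccurrence_fractions)) {
      p$cooccurrence_fractions[[key]] <-
        p$cooccurrence_fractions[[key]] * p$knockdown_factor_flux
    }
  }
  p
}

#' Simulate one multi-channel cyst acquisition with ground truth
#'
#' Builds the three-channel, multi-timepoint volume described by `params`
#' (see [simulation_params()]) and the matching ground truth. Channel 1
#' additionally receives the uniform `background_level` plus
#' `bleed_coefficient` times the noise-free channel-2 signal; noise is
#' applied last. The returned ground truth carries every punctum's center,
#' radius and partner, the cyst mask, the noise-free per-channel signals, and
#' the realized co-occurrence fraction of each ordered channel pair.
#'
#' @param params a [simulation_params()] object.
#' @return A list with elements `volume` (a [VolumeStack]) and `truth`
#'   (class `SyntheticGroundTruth`).
#' @export
simulate_cyst_volume <- function(params) {
  simulate_impl(params, control = FALSE)
}

#' Simulate a matched fluorophore-free control acquisition
#'
#' Identical construction to [simulate_cyst_volume()] — same seed gives the
#' same punctum layout and bit-identical channel-2 and channel-3 planes — but
#' channel 1 contains no true puncta: only `background_level`, bleed-through
#' from channel 2, and noise. These volumes emulate acquisitions of strains
#' lacking the 488-channel fluorophore, used to estimate the background of
#' the contaminated channel.
#'
#' @param params a [simulation_params()] object.
#' @return A [VolumeStack].
#' @export
simulate_control_volume <- function(params) {
  simulate_impl(params, control = TRUE)$volume
}

simulate_impl <- function(params, control) {
  p <- validate_simulation_params(params)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(p$seed)

  layout <- place_objects_retrying(p)
  d <- p$grid_shape
  sp <- p$voxel_spacing
  nt <- p$n_timepoints
  moving <- any(p$drift_um != 0)

  render_t <- function(t) {
    shift <- p$drift_um * (t - 1)
    signals <- vector("list", 3)
    for (ch in 1:3) {
      arr <- array(0, d)
      if (ch >= 2) arr <- arr + p$cyst_fill * layout$cyst_mask
      pp <- layout$puncta[layout$puncta$channel == ch, , drop = FALSE]
      if (nrow(pp) > 0) {
        for (i in seq_len(nrow(pp))) {
          arr <- add_ball(arr, sp, c(pp$cz[i], pp$cy[i], pp$cx[i]) + shift,
                          pp$radius[i], p$peak_intensity)
        }
      }
      if (ch == 3 && nrow(layout$fyve) > 0) {
        for (i in seq_len(nrow(layout$fyve))) {
          arr <- add_ball(arr, sp,
                          c(layout$fyve$cz[i], layout$fyve$cy[i],
                            layout$fyve$cx[i]) + shift,
                          layout$fyve$radius[i], p$fyve_intensity)
        }
      }
      if (any(p$blur_sigma > 0)) arr <- gauss_blur_3d(arr, sp, p$blur_sigma)
      signals[[ch]] <- arr
    }
    signals
  }

  signals0 <- render_t(1)
  data <- array(0, c(d, 3L, nt))
  for (t in seq_len(nt)) {
    signals <- if (moving && t > 1) render_t(t) else signals0
    clean1 <- if (control) {
      p$background_level + p$bleed_coefficient * signals[[2]]
    } else {
      signals[[1]] + p$background_level + p$bleed_coefficient * signals[[2]]
    }
    # channel order 2, 3, 1 so the control shares the generator path (and the
    # exact noise draws) of channels 2-3 with the experimental volume
    data[, , , 2, t] <- add_noise(signals[[2]], p)
    data[, , , 3, t] <- add_noise(signals[[3]], p)
    data[, , , 1, t] <- add_noise(clean1, p)
  }

  vol <- VolumeStack(data, sp, channels = names(p$n_puncta_per_channel))
  truth <- structure(
    list(
      puncta = layout$puncta_labeled,
      fyve = layout$fyve,
      cyst_mask = array(layout$cyst_mask > 0, d),
      cyst_center = layout$cyst_center,
      realized_fractions = realized_cooccurrence(layout, p),
      background_level = p$background_level,
      bleed_coefficient = p$bleed_coefficient,
      clean_signals = setNames(signals0, names(p$n_puncta_per_channel)),
      params = p
    ),
    class = "SyntheticGroundTruth"
  )
  list(volume = vol, truth = truth)
}

#' @export
print.SyntheticGroundTruth <- function(x, ...) {
  n <- table(factor(x$puncta$channel_label,
                    levels = c("ATG9", "ATG8", "FYVE")))
  cat("SyntheticGroundTruth:", sum(n), "puncta (",
      paste(names(n), n, collapse = ", "), "),",
      nrow(x$fyve), "FYVE bodies\n")
  cat("  realized co-occurrence:",
      paste(names(x$realized_fractions),
            signif(x$realized_fractions, 3), collapse = ", "), "\n")
  invisible(x)
}

add_noise <- function(clean, p) {
  out <- clean
  if (p$poisson_gain > 0) {
    out <- rpois(length(out), as.vector(out) * p$poisson_gain) / p$poisson_gain
  }
  if (p$read_noise_sd > 0) {
    out <- out + rnorm(length(out), 0, p$read_noise_sd)
  }
  out <- pmax(out, 0)
  dim(out) <- dim(clean)
  out
}

# ---- placement ------------------------------------------------------------

# The layout is sampled sequentially; a dense draw can jam even when the
# requested counts are feasible, so the whole layout is redrawn a bounded
# number of times before giving up.
place_objects_retrying <- function(p, restarts = 20L) {
  for (k in seq_len(restarts)) {
    layout <- tryCatch(place_objects(p), cystpuncta_placement_error =
                         function(e) NULL)
    if (!is.null(layout)) return(layout)
  }
  abort_placement("the object layout (all restarts exhausted)")
}

abort_placement <- function(what) {
  stop(structure(
    class = c("cystpuncta_placement_error", "error", "condition"),
    list(message = paste0("could not place ", what,
                          " after bounded retries; the cyst is too crowded ",
                          "for the requested object counts and separations"),
         call = sys.call(-1))
  ))
}

inside_ellipsoid <- function(pt, center, semi) {
  sum(((pt - center) / semi)^2) <= 1
}

sample_in_ellipsoid <- function(center, semi, attempts) {
  for (k in seq_len(attempts)) {
    u <- runif(3, -1, 1)
    if (sum(u^2) <= 1) return(center + u * semi)
  }
  abort_placement("a point in the cyst")
}

sample_in_ball <- function(center, radius, attempts = 200L) {
  for (k in seq_len(attempts)) {
    u <- runif(3, -1, 1)
    if (sum(u^2) <= 1) return(center + u * radius)
  }
  abort_placement("a point in a sphere")
}

min_dist2 <- function(pt, mat) {
  if (is.null(mat) || nrow(mat) == 0) return(Inf)
  min((mat[, 1] - pt[1])^2 + (mat[, 2] - pt[2])^2 + (mat[, 3] - pt[3])^2)
}

place_objects <- function(p) {
  d <- p$grid_shape
  sp <- p$voxel_spacing
  center <- (d - 1) / 2 * sp
  semi <- p$cyst_radii
  n <- p$n_puncta_per_channel
  f <- p$cooccurrence_fractions
  rmean <- p$punctum_radius_mean
  rsd <- p$punctum_radius_sd
  draw_radius <- function(k) pmin(0.58, pmax(0.2, rnorm(k, rmean, rsd)))

  # large FYVE bodies, mutually separated, fully inside the cyst
  fyve <- data.frame(fyve_id = integer(0), cz = numeric(0), cy = numeric(0),
                     cx = numeric(0), radius = numeric(0))
  if (p$n_fyve_objects > 0) {
    Rf <- p$fyve_object_radius
    placed <- NULL
    restarts <- 0L
    repeat {
      placed <- matrix(numeric(0), 0, 3)
      ok <- TRUE
      for (i in seq_len(p$n_fyve_objects)) {
        got <- FALSE
        for (k in seq_len(p$max_attempts)) {
          pt <- sample_in_ellipsoid(center, pmax(semi - (Rf + 0.2), 0.05),
                                    p$max_attempts)
          if (min_dist2(pt, placed) >= (2 * Rf + 0.2)^2) {
            placed <- rbind(placed, pt)
            got <- TRUE
            break
          }
        }
        if (!got) { ok <- FALSE; break }
      }
      if (ok) break
      restarts <- restarts + 1L
      if (restarts > 50L) abort_placement("the FYVE organelle bodies")
    }
    fyve <- data.frame(fyve_id = seq_len(nrow(placed)), cz = placed[, 1],
                       cy = placed[, 2], cx = placed[, 3], radius = Rf)
  }
  fyve_centers <- as.matrix(fyve[, c("cz", "cy", "cx")])

  outside_pts <- matrix(numeric(0), 0, 3)  # centers placed outside FYVE bodies
  infyve_pts <- matrix(numeric(0), 0, 3)   # centers placed inside FYVE bodies
  infyve_ch <- integer(0)                  # channel of each in-FYVE center

  clear_of_fyve <- function(pt, r) {
    if (nrow(fyve) == 0) return(TRUE)
    min_dist2(pt, fyve_centers) >= (p$fyve_object_radius + r + 0.2)^2
  }

  place_free <- function(r) {
    for (k in seq_len(p$max_attempts)) {
      pt <- sample_in_ellipsoid(center, pmax(semi - (r + 0.2), 0.05),
                                p$max_attempts)
      if (!clear_of_fyve(pt, r)) next
      if (min_dist2(pt, outside_pts) < p$min_separation^2) next
      outside_pts <<- rbind(outside_pts, pt)
      return(pt)
    }
    abort_placement("a free punctum")
  }

  place_in_fyve <- function(r, obj, channel) {
    inner <- p$fyve_object_radius - r - 0.1
    if (inner <= 0) abort_placement("a punctum inside a FYVE body (body too small)")
    oc <- fyve_centers[obj, ]
    same <- infyve_pts[infyve_ch == channel, , drop = FALSE]
    other <- infyve_pts[infyve_ch != channel, , drop = FALSE]
    for (k in seq_len(p$max_attempts)) {
      pt <- sample_in_ball(oc, inner)
      if (min_dist2(pt, same) < p$fyve_min_separation^2) next
      if (min_dist2(pt, other) < p$fyve_min_separation_cross^2) next
      infyve_pts <<- rbind(infyve_pts, pt)
      infyve_ch <<- c(infyve_ch, channel)
      return(pt)
    }
    abort_placement("a punctum inside a FYVE body")
  }

  new_row <- function(id, channel, pt, r, partner_channel = NA_integer_,
                      partner_id = NA_integer_, fyve_id = NA_integer_) {
    data.frame(punctum_id = id, channel = channel, cz = pt[1], cy = pt[2],
               cx = pt[3], radius = r, partner_channel = partner_channel,
               partner_id = partner_id, fyve_id = fyve_id)
  }

  rows <- list()
  next_id <- 1L
  add_row <- function(row) {
    rows[[length(rows) + 1L]] <<- row
    next_id <<- next_id + 1L
  }

  # channel 2 (ATG8): K23 inside FYVE bodies, the rest free
  k23 <- partner_count(f, "ATG8>FYVE", n[2])
  if (k23 > n[2]) stop("ATG8>FYVE fraction requests more puncta than exist")
  if (k23 > 0 && nrow(fyve) == 0) {
    stop("ATG8>FYVE co-occurrence requested but n_fyve_objects is 0")
  }
  r2 <- draw_radius(n[2])
  ch2_ids <- integer(0)
  ch2_free_ids <- integer(0)
  if (n[2] > 0) {
    for (i in seq_len(n[2])) {
      if (i <= k23) {
        obj <- ((i - 1L) %% nrow(fyve)) + 1L
        pt <- place_in_fyve(r2[i], obj, 2L)
        add_row(new_row(next_id, 2L, pt, r2[i], partner_channel = 3L,
                        partner_id = NA_integer_, fyve_id = obj))
      } else {
        pt <- place_free(r2[i])
        add_row(new_row(next_id, 2L, pt, r2[i]))
        ch2_free_ids <- c(ch2_free_ids, next_id - 1L)
      }
      ch2_ids <- c(ch2_ids, next_id - 1L)
    }
  }

  # channel 1 (ATG9): K12 at free channel-2 partners, K13 inside FYVE, rest free
  k12 <- partner_count(f, "ATG9>ATG8", n[1])
  k13 <- partner_count(f, "ATG9>FYVE", n[1])
  if (k12 > length(ch2_free_ids)) {
    stop("not enough non-FYVE ATG8 puncta to serve as ATG9 partners; ",
         "lower 'ATG9>ATG8' or 'ATG8>FYVE'")
  }
  if (k13 > 0 && nrow(fyve) == 0) {
    stop("ATG9>FYVE co-occurrence requested but n_fyve_objects is 0")
  }
  partners <- if (k12 > 0) sample(ch2_free_ids, k12) else integer(0)
  df_so_far <- function() do.call(rbind, rows)
  if (n[1] > 0) {
    r1 <- draw_radius(n[1])
    for (i in seq_len(n[1])) {
      if (i <= k12) {
        pid <- partners[i]
        prow <- df_so_far()[df_so_far()$punctum_id == pid, ]
        off <- if (p$coloc_offset > 0) {
          sample_in_ball(c(0, 0, 0), p$coloc_offset)
        } else c(0, 0, 0)
        pt <- c(prow$cz, prow$cy, prow$cx) + off
        # partnered puncta copy the partner's radius so the two channels see
        # the same object and >90% voxel overlap is achievable by construction
        add_row(new_row(next_id, 1L, pt, prow$radius, partner_channel = 2L,
                        partner_id = pid))
      } else if (i <= k12 + k13) {
        obj <- ((i - k12 - 1L) %% nrow(fyve)) + 1L
        pt <- place_in_fyve(r1[i], obj, 1L)
        add_row(new_row(next_id, 1L, pt, r1[i], partner_channel = 3L,
                        fyve_id = obj))
      } else {
        pt <- place_free(r1[i])
        add_row(new_row(next_id, 1L, pt, r1[i]))
      }
    }
  }

  # channel 3 (FYVE) small puncta: always free
  if (n[3] > 0) {
    r3 <- draw_radius(n[3])
    for (i in seq_len(n[3])) {
      pt <- place_free(r3[i])
      add_row(new_row(next_id, 3L, pt, r3[i]))
    }
  }

  puncta <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(punctum_id = integer(0), channel = integer(0),
               cz = numeric(0), cy = numeric(0), cx = numeric(0),
               radius = numeric(0), partner_channel = integer(0),
               partner_id = integer(0), fyve_id = integer(0))
  }

  # voxelized cyst mask (voxel centers inside the ellipsoid)
  zs <- ((seq_len(d[1]) - 1) * sp[1] - center[1])^2 / semi[1]^2
  ys <- ((seq_len(d[2]) - 1) * sp[2] - center[2])^2 / semi[2]^2
  xs <- ((seq_len(d[3]) - 1) * sp[3] - center[3])^2 / semi[3]^2
  cyst <- outer(outer(zs, ys, `+`), xs, `+`) <= 1

  labeled <- puncta
  if (nrow(labeled) > 0) {
    labeled$channel_label <- c("ATG9", "ATG8", "FYVE")[labeled$channel]
  } else {
    labeled$channel_label <- character(0)
  }

  list(puncta = puncta, puncta_labeled = labeled, fyve = fyve,
       cyst_mask = cyst * 1, cyst_center = center)
}

# Brute-force center-in-object test over the ground-truth records: a query
# punctum co-occurs with a target channel when its center lies inside any
# target punctum sphere or (for FYVE) any large organelle body.
realized_cooccurrence <- function(layout, p) {
  pu <- layout$puncta
  pairs <- list(c(1L, 2L), c(2L, 1L), c(1L, 3L), c(2L, 3L))
  labs <- c("ATG9", "ATG8", "FYVE")
  out <- numeric(0)
  for (pr in pairs) {
    q <- pu[pu$channel == pr[1], , drop = FALSE]
    tg <- pu[pu$channel == pr[2], , drop = FALSE]
    tc <- as.matrix(tg[, c("cz", "cy", "cx")])
    tr <- tg$radius
    if (pr[2] == 3L && nrow(layout$fyve) > 0) {
      tc <- rbind(tc, as.matrix(layout$fyve[, c("cz", "cy", "cx")]))
      tr <- c(tr, layout$fyve$radius)
    }
    num <- 0L
    if (nrow(q) > 0 && length(tr) > 0) {
      for (i in seq_len(nrow(q))) {
        d2 <- (tc[, 1] - q$cz[i])^2 + (tc[, 2] - q$cy[i])^2 +
          (tc[, 3] - q$cx[i])^2
        if (any(d2 <= tr^2)) num <- num + 1L
      }
    }
    out[paste0(labs[pr[1]], ">", labs[pr[2]])] <-
      if (nrow(q) > 0) num / nrow(q) else NA_real_
  }
  out
}

# Add a solid sphere (voxel centers within `radius` of `center`, um) to an
# array; values accumulate where objects overlap.
add_ball <- function(arr, spacing, center, radius, value) {
  d <- dim(arr)
  lo <- pmax(ceiling((center - radius) / spacing), 0)
  hi <- pmin(floor((center + radius) / spacing), d - 1)
  if (any(lo > hi)) return(arr)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  z2 <- (zi * spacing[1] - center[1])^2
  y2 <- (yi * spacing[2] - center[2])^2
  x2 <- (xi * spacing[3] - center[3])^2
  m <- outer(outer(z2, y2, `+`), x2, `+`) <= radius^2
  block <- arr[zi + 1, yi + 1, xi + 1, drop = FALSE]
  block[m] <- block[m] + value
  arr[zi + 1, yi + 1, xi + 1] <- block
  arr
}
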