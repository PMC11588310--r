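#' Co-occurrence recovery study on simulated cysts
#'
#' For each requested true co-occurrence fraction, simulates `n_cysts` cysts
#' in which that fraction of ATG9 puncta shares centers with distinct ATG8
#' puncta (all other generated pairs switched off so the factor under study
#' is isolated), runs background correction, cyst segmentation, detection,
#' volume filtering and ratio computation, and reports the estimated
#' `ATG9>ATG8` ratio next to the requested and realized truth.
#'
#' @param fractions true fractions to scan.
#' @param n_cysts cysts per fraction.
#' @param params base [simulation_params()]; its `ATG9>ATG8` entry is
#'   overwritten per run and the FYVE pairs are set to zero.
#' @param det_cfg,quant_cfg,bg_cfg stage configurations as in
#'   [run_pipeline()].
#' @param seed master seed.
#' @return `data.frame` with one row per cyst: `fraction`, `cyst`,
#'   `realized`, `estimated`, `n_query_true`, `n_query_detected`.
#' @export
experiment_cooccurrence_recovery <- function(fractions = c(0, 0.25, 0.5, 0.75, 1),
                                             n_cysts = 10L,
                                             params = simulation_params(n_timepoints = 1L),
                                             det_cfg = detection_config(),
                                             quant_cfg = quant_config(),
                                             bg_cfg = detection_config(growth_fraction = 0.6),
                                             seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      2L * length(fractions) * n_cysts)
  k <- 0L
  rows <- list()
  for (f in fractions) {
    for (i in seq_len(n_cysts)) {
      k <- k + 1L
      p <- params
      p$cooccurrence_fractions <- c("ATG9>ATG8" = f, "ATG9>FYVE" = 0,
                                    "ATG8>FYVE" = 0)
      p$seed <- seeds[2L * k - 1L]
      sim <- simulate_cyst_volume(p)
      p_ctrl <- p
      p_ctrl$seed <- seeds[2L * k]
      ctrl <- simulate_control_volume(p_ctrl)
      bg <- estimate_background(ctrl, bg_cfg)
      v <- subtract_background(sim$volume, bg)
      mask <- segment_cyst(v)
      segs <- filter_by_volume(
        detect_puncta(v, det_cfg, mask = mask,
                      channels = c("ATG9", "ATG8"),
                      scale_stack = sim$volume), quant_cfg)
      res <- cooccurrence_ratios(segs, quant_cfg, cyst_id = k)
      pr <- res$pairs
      est <- pr$ratio[pr$query == "ATG9" & pr$target == "ATG8"]
      rows[[k]] <- data.frame(
        fraction = f, cyst = i,
        realized = unname(sim$truth$realized_fractions["ATG9>ATG8"]),
        estimated = est,
        n_query_true = sum(sim$truth$puncta$channel == 1L),
        n_query_detected = pr$denominator[pr$query == "ATG9" &
                                            pr$target == "ATG8"]
      )
    }
  }
  do.call(rbind, rows)
}

#' Bleed-through false-positive study on non-expressing controls
#'
#' Quantifies how control-derived background subtraction suppresses spurious
#' channel-1 detections caused by autofluorescent background and tdTomato
#' bleed-through. Per cyst, two independent control acquisitions are
#' simulated: the background is estimated on the first and the channel-1
#' false-positive count is measured on the second (which contains no true
#' channel-1 puncta), both with and without the correction, under the same
#' detection configuration.
#'
#' @param n_cysts number of control cysts.
#' @param params base [simulation_params()].
#' @param det_cfg,quant_cfg,bg_cfg stage configurations.
#' @param seed master seed.
#' @return `data.frame` with `cyst`, `fp_corrected`, `fp_uncorrected`, and
#'   the estimated mean background `bg_mean`.
#' @export
experiment_bleedthrough_fp <- function(n_cysts = 10L,
                                       params = simulation_params(n_timepoints = 1L),
                                       det_cfg = detection_config(),
                                       quant_cfg = quant_config(),
                                       bg_cfg = detection_config(growth_fraction = 0.6),
                                       seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_cysts)
  rows <- list()
  for (i in seq_len(n_cysts)) {
    p1 <- params; p1$seed <- seeds[2L * i - 1L]
    p2 <- params; p2$seed <- seeds[2L * i]
    ctrl_est <- simulate_control_volume(p1)
    ctrl_eval <- simulate_control_volume(p2)
    bg <- estimate_background(ctrl_est, bg_cfg)
    count_fp <- function(v) {
      mask <- segment_cyst(v)
      segs <- detect_puncta(v, det_cfg, mask = mask, channels = "ATG9",
                            scale_stack = ctrl_eval)
      nrow(filter_by_volume(segs, quant_cfg))
    }
    rows[[i]] <- data.frame(
      cyst = i,
      fp_uncorrected = count_fp(ctrl_eval),
      fp_corrected = count_fp(subtract_background(ctrl_eval, bg)),
      bg_mean = mean(bg$per_timepoint_mean)
    )
  }
  do.call(rbind, rows)
}

#' Mean object-volume recovery against the analytic blurred-sphere model
#'
#' Simulates cysts with no generated co-occurrence, measures the mean
#' detected object volume in the ATG9 and ATG8 channels, and compares it to
#' the analytic expectation from [expected_blob_volume()] averaged over the
#' true punctum radii.
#'
#' @param n_cysts number of cysts.
#' @param params base [simulation_params()].
#' @param det_cfg,quant_cfg,bg_cfg stage configurations.
#' @param seed master seed.
#' @return `data.frame` with one row per cyst and channel: `cyst`, `channel`,
#'   `estimated_mean_volume`, `analytic_mean_volume`, `n_detected`.
#' @export
experiment_volume_recovery <- function(n_cysts = 10L,
                                       params = simulation_params(n_timepoints = 1L),
                                       det_cfg = detection_config(),
                                       quant_cfg = quant_config(),
                                       bg_cfg = detection_config(growth_fraction = 0.6),
                                       seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_cysts)
  rows <- list()
  k <- 0L
  for (i in seq_len(n_cysts)) {
    p <- params
    p$cooccurrence_fractions <- c("ATG9>ATG8" = 0, "ATG9>FYVE" = 0,
                                  "ATG8>FYVE" = 0)
    p$seed <- seeds[2L * i - 1L]
    sim <- simulate_cyst_volume(p)
    p_ctrl <- p; p_ctrl$seed <- seeds[2L * i]
    ctrl <- simulate_control_volume(p_ctrl)
    bg <- estimate_background(ctrl, bg_cfg)
    v <- subtract_background(sim$volume, bg)
    mask <- segment_cyst(v)
    segs <- filter_by_volume(
      detect_puncta(v, det_cfg, mask = mask, channels = c("ATG9", "ATG8"),
                    scale_stack = sim$volume),
      quant_cfg)
    for (ch in c("ATG9", "ATG8")) {
      chnum <- match(ch, c("ATG9", "ATG8", "FYVE"))
      radii <- sim$truth$puncta$radius[sim$truth$puncta$channel == chnum]
      analytic <- mean(vapply(radii, expected_blob_volume, 0,
                              blur_sigma = p$blur_sigma, cfg = det_cfg))
      chseg <- segs[segs$channel == ch, , drop = FALSE]
      k <- k + 1L
      rows[[k]] <- data.frame(
        cyst = i, channel = ch,
        estimated_mean_volume = mean_object_volume(chseg),
        analytic_mean_volume = analytic,
        n_detected = nrow(chseg)
      )
    }
  }
  do.call(rbind, rows)
}
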