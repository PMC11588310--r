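#' Radial profile of a Gaussian-blurred solid ball
#'
#' Closed-form intensity profile of a unit-intensity solid sphere of radius
#' `radius` convolved with an isotropic 3D Gaussian of standard deviation
#' `sigma`, evaluated at distance `d` from the sphere center:
#' \deqn{C(d) = \tfrac12\left[\mathrm{erf}\!\frac{R-d}{\sigma\sqrt2} +
#'   \mathrm{erf}\!\frac{R+d}{\sigma\sqrt2}\right] +
#'   \frac{\sigma}{d\sqrt{2\pi}}\left[e^{-(R+d)^2/2\sigma^2} -
#'   e^{-(R-d)^2/2\sigma^2}\right]}
#' with the limit \eqn{C(0) = \mathrm{erf}(R/\sigma\sqrt2) -
#' \sqrt{2/\pi}\,(R/\sigma)\,e^{-R^2/2\sigma^2}}. This is the idealized image
#' of a punctum rendered as a uniform sphere and blurred by the simulated
#' optics, and underpins the analytic object-volume oracle used to validate
#' volume recovery.
#'
#' @param d numeric vector of distances from the sphere center (um).
#' @param radius sphere radius (um).
#' @param sigma Gaussian standard deviation (um).
#' @return numeric vector of profile values in `[0, 1]`.
#' @export
blurred_ball_profile <- function(d, radius, sigma) {
  stopifnot(radius > 0, sigma > 0, all(d >= 0))
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  out <- numeric(length(d))
  near0 <- d < 1e-9
  if (any(near0)) {
    out[near0] <- erf(radius / (sigma * sqrt(2))) -
      sqrt(2 / pi) * (radius / sigma) * exp(-radius^2 / (2 * sigma^2))
  }
  if (any(!near0)) {
    dd <- d[!near0]
    out[!near0] <-
      0.5 * (erf((radius - dd) / (sigma * sqrt(2))) +
             erf((radius + dd) / (sigma * sqrt(2)))) +
      sigma / (dd * sqrt(2 * pi)) *
        (exp(-(radius + dd)^2 / (2 * sigma^2)) -
         exp(-(radius - dd)^2 / (2 * sigma^2)))
  }
  out
}

#' Expected segmented volume of a blurred spherical punctum
#'
#' Predicts, from the continuous image-formation model, the volume that
#' [segment_blobs()] recovers for an isolated spherical punctum: the punctum
#' (radius `radius`, blurred by the acquisition at `blur_sigma`) is passed
#' through the band-pass enhancer at the configured scales, and the segment is
#' the region where the enhanced response exceeds `growth_fraction` of its
#' peak. Because sphere, blur and enhancer are all radially symmetric (for an
#' isotropic `blur_sigma`), that region is a ball whose radius solves
#' `response(r) = growth_fraction * response(0)` with the closed-form profile
#' of [blurred_ball_profile()].
#'
#' @param radius true sphere radius (um).
#' @param blur_sigma acquisition blur standard deviation (um); if a vector is
#'   given, its geometric mean is used (the prediction assumes isotropy).
#' @param cfg a [detection_config()]; its first enhancement scale and its
#'   `growth_fraction` define the operator.
#' @return expected segment volume in um^3.
#' @export
expected_blob_volume <- function(radius, blur_sigma, cfg = detection_config()) {
  stopifnot(radius > 0)
  bs <- exp(mean(log(blur_sigma)))
  sg <- dog_sigmas(cfg$enhancement_scales[1])
  s_in <- sqrt(bs^2 + sg[["inner"]]^2)
  s_out <- sqrt(bs^2 + sg[["outer"]]^2)
  resp <- function(d) {
    blurred_ball_profile(d, radius, s_in) - blurred_ball_profile(d, radius, s_out)
  }
  peak <- resp(0)
  target <- cfg$growth_fraction * peak
  upper <- radius + 6 * s_out
  r_g <- uniroot(function(d) resp(d) - target,
                 lower = 1e-9, upper = upper, tol = 1e-10)$root
  4 / 3 * pi * r_g^3
}
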