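#' Natural-scene and self-motion statistics
#'
#' Natural scenes have a 1/f² spatial power spectrum,
#' `S_xy = c_c / f_r^2`. The constant `c_c` is set so that the local
#' contrast over a fixed band of spatial frequencies (one cycle per 50
#' degrees up to one cycle per 1.5 degrees by default) equals `contrast`
#' (0.4, as measured through a blowfly eye). Image motion follows a
#' long-tailed angular-speed distribution of width `sigma_v`.
#'
#' @param contrast target local RMS contrast (default 0.4).
#' @param sigma_v width of the angular-velocity distribution, rad s⁻¹
#'   (default 1; 0.29 is the value assumed in earlier work and available
#'   via `scene_model(sigma_v = 0.29)`).
#' @param band_lo_deg,band_hi_deg edges of the contrast-normalisation band
#'   expressed as degrees per cycle (defaults 50 and 1.5).
#' @return object of class `scene_model` with fields `c_c`, `sigma_v`,
#'   `contrast`, `band_lo`, `band_hi` (band edges in cycles per radian).
#' @export
scene_model <- function(contrast = 0.4, sigma_v = 1,
                        band_lo_deg = 50, band_hi_deg = 1.5) {
  stopifnot(contrast > 0, sigma_v > 0, band_lo_deg > band_hi_deg,
            band_hi_deg > 0)
  band_lo <- 1 / deg_to_rad(band_lo_deg)
  band_hi <- 1 / deg_to_rad(band_hi_deg)
  structure(list(
    contrast = contrast, sigma_v = sigma_v,
    band_lo = band_lo, band_hi = band_hi,
    c_c = contrast_constant(contrast, band_lo, band_hi)),
    class = "scene_model")
}

#' Scene-spectrum proportionality constant
#'
#' The 2-D integral of `c_c / f_r^2` over the annulus
#' `band_lo <= f_r <= band_hi` is `2 pi c_c ln(band_hi/band_lo)`; setting
#' it to `contrast^2` gives the closed form
#' `c_c = contrast^2 / (2 pi ln(band_hi/band_lo))`.
#'
#' @param contrast target RMS contrast over the band.
#' @param band_lo,band_hi band edges, cycles per radian.
#' @return `c_c` in contrast² units.
#' @export
contrast_constant <- function(contrast, band_lo, band_hi) {
  stopifnot(contrast > 0, band_lo > 0, band_hi > band_lo)
  contrast^2 / (2 * pi * log(band_hi / band_lo))
}

#' Angular-velocity probability density
#'
#' `a_v(v) = c_v / (|v| + sigma_v)^2` with `c_v = sigma_v / 2`, which makes
#' the density integrate to one over the whole real line.
#'
#' @param v angular speed, radians per second (signed).
#' @param sigma_v width constant, radians per second.
#' @return probability density, seconds per radian.
#' @export
velocity_pdf <- function(v, sigma_v = 1) {
  stopifnot(all(sigma_v > 0))
  (sigma_v / 2) / (abs(v) + sigma_v)^2
}

#' Spatio-temporal power density of natural signals
#'
#' Rigid image motion converts spatial into temporal frequency; folding the
#' velocity distribution through the 1/f² scene spectrum gives
#' \deqn{S_{xyt}(f_r, f_t) = \frac{\pi}{2 f_r^3} c_c\,
#'       a_v\!\left(\frac{\pi}{2}\frac{f_t}{f_r}\right).}
#' Even in `f_t`; its temporal marginal recovers the spatial spectrum
#' `c_c / f_r^2`.
#'
#' @param f_r radial spatial frequency, cycles per radian (> 0).
#' @param f_t temporal frequency, hertz.
#' @param scene a [scene_model()].
#' @return power density.
#' @export
spatiotemporal_spectrum <- function(f_r, f_t, scene = scene_model()) {
  stopifnot(inherits(scene, "scene_model"))
  if (any(f_r <= 0)) stop("f_r must be positive (spectrum diverges at the origin)")
  pi / (2 * f_r^3) * scene$c_c *
    velocity_pdf(pi / 2 * f_t / f_r, scene$sigma_v)
}
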