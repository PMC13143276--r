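#' Optical model for the photoreceptor acceptance angle
#'
#' Two approximations for the half-width of the photoreceptor angular
#' sensitivity: `"COG"` (convolution of Gaussians) adds the Airy-disk
#' half-width `lambda/D` and the rhabdomere subtense `d_rh/f` in
#' quadrature; `"WOM"` (wave-optics model) uses `coef * lambda / D`, with
#' the coefficient 1.26 appropriate for a fly eye whose longitudinal pupil
#' is partly closed in daylight (it falls to 1.14 when fully closed).
#'
#' @param mode `"COG"` or `"WOM"`.
#' @param lambda wavelength of light, micrometres (default 0.5).
#' @param wom_coefficient multiple of the diffraction limit used by the
#'   wave-optics approximation (default 1.26).
#' @return object of class `optical_model`.
#' @export
optical_model <- function(mode = c("COG", "WOM"), lambda = 0.5,
                          wom_coefficient = 1.26) {
  mode <- match.arg(mode)
  stopifnot(lambda > 0, wom_coefficient >= 1)
  structure(list(mode = mode, lambda = lambda,
                 wom_coefficient = wom_coefficient),
            class = "optical_model")
}

#' Photoreceptor acceptance angle
#'
#' @param model an [optical_model()].
#' @param D lens diameter, micrometres.
#' @param f focal length in air, micrometres (used by COG).
#' @param d_rh rhabdom(ere) diameter, micrometres (used by COG).
#' @return acceptance half-width, radians.
#' @export
acceptance_angle <- function(model, D, f, d_rh) {
  stopifnot(inherits(model, "optical_model"), all(D > 0), all(f > 0),
            all(d_rh >= 0))
  if (model$mode == "COG") {
    sqrt((model$lambda / D)^2 + (d_rh / f)^2)
  } else {
    model$wom_coefficient * model$lambda / D
  }
}

#' Gaussian spatial transfer function
#'
#' Amplitude transfer of a Gaussian angular-sensitivity profile of
#' half-width `delta_rho`:
#' \deqn{m(f_r) = \exp(-\pi^2 f_r^2 \Delta\rho^2 / (4 \ln 2))}
#' Radially symmetric, so it takes the radial spatial frequency. The power
#' transfer is its square.
#'
#' @param f_r radial spatial frequency, cycles per radian.
#' @param delta_rho acceptance half-width, radians.
#' @return transfer amplitude in `[0, 1]`.
#' @export
spatial_mtf <- function(f_r, delta_rho) {
  stopifnot(all(delta_rho > 0))
  exp(-pi^2 / (4 * log(2)) * f_r^2 * delta_rho^2)
}
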