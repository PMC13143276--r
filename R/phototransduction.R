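#' Phototransduction model constants
#'
#' Parameters of the transduction cascade of a fully light-adapted fly
#' photoreceptor: microvillus packing density along the rhabdomere, the
#' microvillus cycling (refractory) time, the quantum-bump shape filter
#' (log-normal-like impulse response of time constant `tau` and exponent
#' `alpha`) and the bump latency-dispersion filter (`tau_d`, `alpha_d`).
#'
#' `tau_r` is not directly measured; its default (0.1 s) sets the
#' half-saturation transduction rate. It scales signal as `psi^2` and shot
#' noise as `psi`, shifting absolute capacity but moving optima only
#' weakly; it is reported in all outputs.
#'
#' @param nu microvilli per micrometre of rhabdomere (default 230).
#' @param tau_r microvillus cycling time, seconds (default 0.1).
#' @param tau bump time constant, seconds (default 0.001).
#' @param alpha bump shape exponent (default 3.12).
#' @param tau_d latency-dispersion time constant, seconds (default 0.0014).
#' @param alpha_d latency filter exponent (default 2).
#' @return object of class `photoreceptor_model`.
#' @export
photoreceptor_model <- function(nu = 230, tau_r = 0.1, tau = 0.001,
                                alpha = 3.12, tau_d = 0.0014, alpha_d = 2) {
  stopifnot(nu > 0, tau_r > 0, tau > 0, alpha > 1, tau_d > 0, alpha_d > 0)
  structure(list(nu = nu, tau_r = tau_r, tau = tau, alpha = alpha,
                 tau_d = tau_d, alpha_d = alpha_d),
            class = "photoreceptor_model")
}

#' Quantum-bump temporal power filter
#'
#' Power transfer of the bump impulse response:
#' `|m_t(f)|^2 = 1 / (1 + (2 pi tau f)^2)^alpha`.
#'
#' @param f_t temporal frequency, hertz.
#' @param tau bump time constant, seconds.
#' @param alpha bump shape exponent.
#' @return power transfer in `(0, 1]`.
#' @export
bump_filter_power <- function(f_t, tau = 0.001, alpha = 3.12) {
  stopifnot(all(tau > 0))
  1 / (1 + (2 * pi * tau * f_t)^2)^alpha
}

#' Bump latency-dispersion power filter
#'
#' `|m_d(f)|^2 = 1 / (1 + (2 pi tau_d f)^2)^alpha_d`. Together with the
#' bump filter it reproduces the ~55 Hz signal corner frequency of a
#' light-adapted blowfly photoreceptor.
#'
#' @param f_t temporal frequency, hertz.
#' @param tau_d latency time constant, seconds.
#' @param alpha_d latency exponent.
#' @return power transfer in `(0, 1]`.
#' @export
latency_filter_power <- function(f_t, tau_d = 0.0014, alpha_d = 2) {
  stopifnot(all(tau_d > 0))
  1 / (1 + (2 * pi * tau_d * f_t)^2)^alpha_d
}

#' Photoreceptor signal-to-noise ratio at half-saturation
#'
#' With microvilli held at half-saturation by the pupil mechanism, bump
#' statistics are binomial and `SNR = sqrt(N_vil) / 2` per unit contrast.
#'
#' @param N_vil number of microvilli.
#' @return signal-to-noise ratio per unit contrast.
#' @export
binomial_snr <- function(N_vil) {
  stopifnot(all(N_vil >= 0))
  0.5 * sqrt(N_vil)
}

#' Transduction rate at half-saturation
#'
#' At half-saturation each microvillus completes a bump every two cycling
#' times: `psi = N_vil / (2 tau_r)` bumps per second.
#'
#' @param N_vil number of microvilli.
#' @param tau_r microvillus cycling time, seconds.
#' @return transduction rate, bumps per second.
#' @export
half_saturation_rate <- function(N_vil, tau_r = 0.1) {
  stopifnot(all(N_vil >= 0), all(tau_r > 0))
  N_vil / (2 * tau_r)
}

#' Pixel signal multiplicity
#'
#' The coherent signal prefactor per pixel: an NS pixel pools six
#' photoreceptors, each transducing at `psi`, giving amplitude `3 psi`
#' (the half-saturation derivative contributes the 1/2); fused-rhabdom and
#' simple-eye pixels pool half the transduction units, giving `3 psi / 2`.
#'
#' @param eye_type `"NS"`, `"FUSED"` or `"SIMPLE"`.
#' @return multiplicity `M` such that signal power is `(M psi)^2` and pixel
#'   shot-noise power is `M psi`.
#' @export
pixel_multiplicity <- function(eye_type) {
  switch(eye_type, NS = 3, FUSED = 1.5, SIMPLE = 1.5,
         stop("unknown eye_type: ", eye_type))
}

# Per-rhabdomere-equivalent transduction rate for a geometry.
pixel_psi <- function(geom, prm) {
  half_saturation_rate(prm$nu * geom$L, prm$tau_r)
}

#' Signal power density coded by one pixel
#'
#' The naturalistic spectrum, low-pass filtered by the optics and the two
#' transduction filters, scaled by the pixel's coherent transduction
#' amplitude:
#' \deqn{(\Delta S)^2 = (M\psi)^2 S_{xyt} |m|^2 |m_t|^2 |m_d|^2}
#' with `psi = nu L / (2 tau_r)` per rhabdomere-equivalent and `M` from
#' [pixel_multiplicity()].
#'
#' @param f_r radial spatial frequency, cycles per radian.
#' @param f_t temporal frequency, hertz.
#' @param geom an [eye_geometry()].
#' @param scene a [scene_model()].
#' @param optics an [optical_model()].
#' @param prm a [photoreceptor_model()].
#' @return signal power density.
#' @export
signal_spectrum <- function(f_r, f_t, geom, scene = scene_model(),
                            optics = optical_model(),
                            prm = photoreceptor_model()) {
  psi <- pixel_psi(geom, prm)
  if (psi == 0) return(0 * f_r * f_t)
  M <- pixel_multiplicity(geom$eye_type)
  drho <- acceptance_angle(optics, geom$D, geom$f, geom$d_rh)
  (M * psi)^2 * spatiotemporal_spectrum(f_r, f_t, scene) *
    spatial_mtf(f_r, drho)^2 *
    bump_filter_power(f_t, prm$tau, prm$alpha) *
    latency_filter_power(f_t, prm$tau_d, prm$alpha_d)
}

#' Shot-noise power density over the sampled disc
#'
#' The pixel shot-noise power `M psi |m_t|^2` (uncorrelated across the
#' photoreceptors pooled by a pixel) is spread uniformly over the disc of
#' spatial frequencies the hexagonal array samples, of radius
#' `mu_s = 1/(sqrt(3) delta_phi)` and area `A_s = pi mu_s^2`; the returned
#' density is constant inside the disc and zero outside.
#'
#' @inheritParams signal_spectrum
#' @return noise power density inside the sampled disc.
#' @export
shot_noise_spectrum <- function(f_t, geom, prm = photoreceptor_model()) {
  psi <- pixel_psi(geom, prm)
  M <- pixel_multiplicity(geom$eye_type)
  A_s <- pi * hexagonal_cutoff(geom$delta_phi)^2
  M * psi * bump_filter_power(f_t, prm$tau, prm$alpha) / A_s
}

# Out-of-band filtered spatial signal power per unit temporal frequency:
# integral over f' in [mu_s, f_cut] of 2 pi f' S_xyt(f', f_t) |m(f')|^2,
# evaluated by Gauss-Legendre in log f'. f_t may be a vector; returns a
# vector of the same length.
aliased_power <- function(f_t, mu_s, f_cut, drho, scene, n_nodes = 64) {
  if (f_cut <= mu_s) return(rep(0, length(f_t)))
  gl <- pracma::gaussLegendre(n_nodes, log(mu_s), log(f_cut))
  fp <- exp(gl$x)                       # f' nodes
  # integrand in u = log f': 2 pi f'^2 S_xyt(f', f_t) m(f')^2
  m2 <- spatial_mtf(fp, drho)^2
  base <- 2 * pi * fp^2 * pi / (2 * fp^3) * scene$c_c * m2  # x a_v(...)
  av <- velocity_pdf(outer(fp, f_t, function(a, b) pi / 2 * b / a),
                     scene$sigma_v)
  as.numeric(crossprod(gl$w * base, av))
}

#' Aliasing noise power density
#'
#' Spatial frequencies beyond the array cutoff `mu_s` that survive optical
#' blur are aliased into the sampled band; they are treated as noise shared
#' equally across the sampled disc. The out-of-band signal power (identically
#' filtered, same pixel multiplicity) is integrated from `mu_s` to `f_cut`
#' and divided by the disc area.
#'
#' @inheritParams signal_spectrum
#' @param f_cut upper integration limit, cycles per radian; defaults to
#'   `3 / delta_rho`, beyond which the squared MTF is below 1e-15.
#' @param n_nodes quadrature nodes for the out-of-band integral.
#' @return aliasing noise power density (per unit area of the sampled disc).
#' @export
aliasing_spectrum <- function(f_t, geom, scene = scene_model(),
                              optics = optical_model(),
                              prm = photoreceptor_model(),
                              f_cut = NULL, n_nodes = 64) {
  psi <- pixel_psi(geom, prm)
  if (psi == 0) return(rep(0, length(f_t)))
  M <- pixel_multiplicity(geom$eye_type)
  drho <- acceptance_angle(optics, geom$D, geom$f, geom$d_rh)
  mu_s <- hexagonal_cutoff(geom$delta_phi)
  if (is.null(f_cut)) f_cut <- 3 / drho
  if (f_cut <= mu_s) return(rep(0, length(f_t)))
  A_s <- pi * mu_s^2
  (M * psi)^2 *
    bump_filter_power(f_t, prm$tau, prm$alpha) *
    latency_filter_power(f_t, prm$tau_d, prm$alpha_d) *
    aliased_power(f_t, mu_s, f_cut, drho, scene, n_nodes) / A_s
}
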