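#' Spatial sampling limits of a hexagonal photoreceptor lattice
#'
#' A hexagonal lattice of pitch `delta_phi` samples spatial frequencies up
#' to `mu_s = 1/(sqrt(3) delta_phi)` independently of stimulus orientation.
#'
#' @param delta_phi interommatidial angle, radians.
#' @return orientation-independent cutoff, cycles per radian.
#' @seealso [nyquist_limit()] for the 1-D Nyquist frequency.
#' @export
hexagonal_cutoff <- function(delta_phi) {
  stopifnot(all(delta_phi > 0))
  1 / (sqrt(3) * delta_phi)
}

#' One-dimensional Nyquist limit of a receptor row
#'
#' @param delta_phi receptor spacing, radians.
#' @return Nyquist frequency `1/(2 delta_phi)`, cycles per radian.
#' @export
nyquist_limit <- function(delta_phi) {
  stopifnot(all(delta_phi > 0))
  1 / (2 * delta_phi)
}

#' Quadrature settings for the information integral
#'
#' The capacity integral runs over radial spatial frequency (log-spaced
#' Gauss-Legendre nodes from `mu_s * fr_floor` to `mu_s`; the integrand
#' `f_r log2(1 + S/N)` vanishes toward the origin despite the 1/f_r^3
#' spectrum) and temporal frequency (Gauss-Legendre panels splitting
#' `[0, ft_max]` logarithmically to resolve the slow low-frequency
#' structure, doubled outward until the tail adds less than `tail_tol` of
#' the running total). Everything is deterministic.
#'
#' @param fr_nodes spatial nodes (default 64).
#' @param ft_nodes temporal nodes per panel (default 48).
#' @param ft_max initial temporal integration limit, hertz (default 2000).
#' @param tail_tol stop extending the temporal range when a doubling adds
#'   less than this fraction of the total (default 1e-4).
#' @param fr_floor lower spatial limit as a fraction of `mu_s`.
#' @param f_cut_factor aliasing integration extends to
#'   `f_cut_factor / delta_rho` (default 3).
#' @param max_doublings cap on temporal-range doublings.
#' @return list of class `capacity_control`.
#' @export
capacity_control <- function(fr_nodes = 64, ft_nodes = 48, ft_max = 2000,
                             tail_tol = 1e-4, fr_floor = 1e-4,
                             f_cut_factor = 3, max_doublings = 8) {
  stopifnot(fr_nodes >= 8, ft_nodes >= 8, ft_max > 0, tail_tol > 0,
            fr_floor > 0, fr_floor < 1, f_cut_factor > 0)
  structure(list(fr_nodes = fr_nodes, ft_nodes = ft_nodes, ft_max = ft_max,
                 tail_tol = tail_tol, fr_floor = fr_floor,
                 f_cut_factor = f_cut_factor, max_doublings = max_doublings),
            class = "capacity_control")
}

# Log-spaced Gauss-Legendre nodes and weights for the radial integral
# of g(f_r) df_r over [mu_s*floor, mu_s]: substitute u = log f_r, so the
# weight carries the extra factor f_r.
fr_log_nodes <- function(mu_s, n, floor_frac = 1e-4) {
  gl <- pracma::gaussLegendre(n, log(mu_s * floor_frac), log(mu_s))
  fr <- exp(gl$x)
  list(fr = fr, w = gl$w * fr)
}

# One temporal Gauss-Legendre panel of the capacity integrand:
# returns the integral over f_t in [a, b] of
#   int f_r log2(1 + SNR(f_r, f_t)) df_r.
# SNR = A_s M psi S_xyt m^2 md^2 / (1 + M psi md^2 A(f_t)); the bump
# filter |m_t|^2 multiplies signal and both noise terms and cancels.
capacity_panel <- function(a, b, frq, Mpsi, A_s, drho, mu_s, f_cut,
                           scene, prm, n_ft, n_alias) {
  gl <- pracma::gaussLegendre(n_ft, a, b)
  ft <- gl$x
  md2 <- latency_filter_power(ft, prm$tau_d, prm$alpha_d)
  A_al <- aliased_power(ft, mu_s, f_cut, drho, scene, n_alias)
  m2 <- spatial_mtf(frq$fr, drho)^2
  # S_xyt over the fr x ft grid
  S <- pi / (2 * frq$fr^3) * scene$c_c *
    velocity_pdf(outer(frq$fr, ft, function(a., b.) pi / 2 * b. / a.),
                 scene$sigma_v)
  snr <- sweep(S * (A_s * Mpsi * m2), 2,
               md2 / (1 + Mpsi * md2 * A_al), `*`)
  # integrand is f_r log2(1 + S/N); frq$w already carries the d(f_r) weight
  g <- as.numeric(crossprod(frq$w * frq$fr, log2(1 + snr)))
  sum(gl$w * g)
}

capacity_core <- function(geom, scene, optics, prm, control) {
  psi <- pixel_psi(geom, prm)
  if (psi == 0 || geom$L == 0) {
    return(list(H = 0, ft_max_used = 0, truncation = 0))
  }
  M <- pixel_multiplicity(geom$eye_type)
  Mpsi <- M * psi
  drho <- acceptance_angle(optics, geom$D, geom$f, geom$d_rh)
  mu_s <- hexagonal_cutoff(geom$delta_phi)
  A_s <- pi * mu_s^2
  f_cut <- control$f_cut_factor / drho
  frq <- fr_log_nodes(mu_s, control$fr_nodes, control$fr_floor)
  n_al <- max(32, control$fr_nodes %/% 2)
  # split [0, ft_max] into log-graded panels to resolve low frequencies
  edges <- c(0, control$ft_max / 100, control$ft_max / 10, control$ft_max)
  H_half <- 0
  for (i in seq_len(length(edges) - 1)) {
    H_half <- H_half + capacity_panel(
      edges[i], edges[i + 1], frq, Mpsi, A_s, drho, mu_s, f_cut,
      scene, prm, control$ft_nodes, n_al)
  }
  # extend the temporal range until the tail is negligible
  lo <- control$ft_max
  tail_frac <- Inf
  for (k in seq_len(control$max_doublings)) {
    tail <- capacity_panel(lo, 2 * lo, frq, Mpsi, A_s, drho, mu_s, f_cut,
                           scene, prm, control$ft_nodes, n_al)
    tail_frac <- tail / max(H_half, .Machine$double.xmin)
    H_half <- H_half + tail
    lo <- 2 * lo
    if (tail_frac < control$tail_tol) break
  }
  if (tail_frac >= control$tail_tol) {
    warning(sprintf(
      "temporal integral not converged: last doubling added %.2g of total",
      tail_frac))
  }
  list(H = 2 * sqrt(3) * 2 * H_half, ft_max_used = lo, truncation = tail_frac)
}

#' Spatio-temporal information capacity of a photoreceptor array
#'
#' Numerically evaluates
#' \deqn{H = 2\sqrt{3} \int_{-\infty}^{\infty}\!\!\int_0^{\mu_s}
#'  f_r \log_2\!\left(1 + \frac{(\Delta S)^2}{\sigma_{sn}^2 +
#'  \sigma_{al}^2}\right) df_r\, df_t}
#' in bits sr⁻¹ s⁻¹, with the pixel signal, shot-noise and aliasing spectra
#' of [signal_spectrum()], [shot_noise_spectrum()] and
#' [aliasing_spectrum()]. The integrand is even in `f_t`, so twice the
#' positive half is computed. The prefactor `2 sqrt(3)` is fixed by the
#' requirement that a frequency-independent S/N reproduce
#' (pixels per steradian) x log2 sqrt(1 + S/N).
#'
#' @param geom an [eye_geometry()] with `L > 0` for a nonzero result.
#' @param scene a [scene_model()].
#' @param optics an [optical_model()].
#' @param prm a [photoreceptor_model()].
#' @param control a [capacity_control()].
#' @param diagnostics if `TRUE`, recompute at doubled node counts and
#'   report the relative difference as `convergence`.
#' @return object of class `capacity_result`: list with `H` (bits sr⁻¹
#'   s⁻¹), `mu_s`, `psi`, `ft_max_used`, `truncation` (tail fraction) and,
#'   with `diagnostics`, `convergence`.
#' @examples
#' g <- eye_geometry("NS", D = 25, L = 200, delta_phi = deg_to_rad(1.5))
#' information_capacity(g)$H
#' @export
information_capacity <- function(geom, scene = scene_model(),
                                 optics = optical_model(),
                                 prm = photoreceptor_model(),
                                 control = capacity_control(),
                                 diagnostics = FALSE) {
  stopifnot(inherits(geom, "eye_geometry"))
  res <- capacity_core(geom, scene, optics, prm, control)
  out <- list(H = res$H, mu_s = hexagonal_cutoff(geom$delta_phi),
              psi = pixel_psi(geom, prm),
              ft_max_used = res$ft_max_used, truncation = res$truncation,
              fr_nodes = control$fr_nodes, ft_nodes = control$ft_nodes)
  if (diagnostics) {
    fine <- control
    fine$fr_nodes <- 2 * control$fr_nodes
    fine$ft_nodes <- 2 * control$ft_nodes
    H2 <- capacity_core(geom, scene, optics, prm, fine)$H
    out$convergence <- if (H2 > 0) abs(out$H - H2) / H2 else 0
    out$H_refined <- H2
  }
  structure(out, class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> H = %.6g bits/sr/s (mu_s = %.3g cyc/rad)\n",
              x$H, x$mu_s))
  if (!is.null(x$convergence)) {
    cat(sprintf("  quadrature-doubling change: %.2g relative\n",
                x$convergence))
  }
  invisible(x)
}
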