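# Shared fixtures for the test suite. Everything is generated in code;
# grids are kept small here (the acceptance tests use the full defaults).

small_grid <- function() morphospace_grid(D_range = c(8, 150),
                                          L_range = c(30, 3000),
                                          nD = 15, nL = 15)

# Reference NS geometry used for convergence checks.
ref_ns_geometry <- function() {
  eye_geometry("NS", D = 25, L = 200, delta_phi = deg_to_rad(1.5))
}

# Draw n random feasible apposition geometries (R, f', L) for property
# tests: R comfortably larger than f' + L.
random_shells <- function(n, seed = 421) {
  set.seed(seed)
  f_prime <- runif(n, 0, 500)
  L <- runif(n, 0, 2000)
  R <- (f_prime + L) * (1 + rexp(n, rate = 2))
  list(R = R, f_prime = f_prime, L = L)
}

# Brute-force Riemann evaluation of the capacity integral, built directly
# from the exported spectrum functions (signal, shot noise, aliasing with
# stats::integrate for the out-of-band power) -- independent of the
# package's nested Gauss-Legendre path.
riemann_capacity <- function(geom, n_fr = 600, n_ft = 500, ft_max = 2000,
                             scene = scene_model(),
                             optics = optical_model(),
                             prm = photoreceptor_model()) {
  mu_s <- hexagonal_cutoff(geom$delta_phi)
  drho <- acceptance_angle(optics, geom$D, geom$f, geom$d_rh)
  f_cut <- 3 / drho
  M <- pixel_multiplicity(geom$eye_type)
  psi <- half_saturation_rate(prm$nu * geom$L, prm$tau_r)
  A_s <- pi * mu_s^2
  fr <- exp(seq(log(mu_s * 1e-5), log(mu_s), length.out = n_fr))
  ft <- seq(0, ft_max, length.out = n_ft)
  out_band <- vapply(ft, function(t) {
    if (f_cut <= mu_s) return(0)
    integrate(function(f) {
      2 * pi * f * spatiotemporal_spectrum(f, t, scene) *
        spatial_mtf(f, drho)^2
    }, mu_s, f_cut, rel.tol = 1e-9)$value
  }, numeric(1))
  g <- vapply(seq_along(ft), function(j) {
    sig <- (M * psi)^2 * spatiotemporal_spectrum(fr, ft[j], scene) *
      spatial_mtf(fr, drho)^2 *
      bump_filter_power(ft[j], prm$tau, prm$alpha) *
      latency_filter_power(ft[j], prm$tau_d, prm$alpha_d)
    shot <- M * psi * bump_filter_power(ft[j], prm$tau, prm$alpha) / A_s
    alias <- (M * psi)^2 * bump_filter_power(ft[j], prm$tau, prm$alpha) *
      latency_filter_power(ft[j], prm$tau_d, prm$alpha_d) *
      out_band[j] / A_s
    y <- fr * log2(1 + sig / (shot + alias))
    # trapezoid in log f_r (extra factor f_r from the substitution)
    u <- log(fr)
    sum(diff(u) * (y[-1] * fr[-1] + y[-n_fr] * fr[-n_fr]) / 2)
  }, numeric(1))
  2 * sqrt(3) * 2 * sum(diff(ft) * (g[-1] + g[-n_ft]) / 2)
}
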