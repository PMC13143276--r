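test_that("temporal filters are unity at DC, even, and monotone", {
  expect_equal(bump_filter_power(0), 1)
  expect_equal(latency_filter_power(0), 1)
  ft <- seq(0, 500, by = 5)
  expect_true(all(diff(bump_filter_power(ft)) < 0))
  expect_true(all(diff(latency_filter_power(ft)) < 0))
  expect_equal(bump_filter_power(-77), bump_filter_power(77))
  expect_equal(latency_filter_power(-77), latency_filter_power(77))
})

test_that("filter corner frequencies match numeric root-finding oracles", {
  # bump filter half-power for tau = 1 ms, alpha = 3.12
  f_half <- uniroot(function(f) bump_filter_power(f) - 0.5, c(10, 500),
                    tol = 1e-10)$root
  expect_equal(f_half, 79.4, tolerance = 1e-2)
  # alpha = 1 reduces to a Lorentzian with half-power at 1/(2 pi tau)
  tau <- 0.002
  expect_equal(bump_filter_power(1 / (2 * pi * tau), tau, 1), 0.5)
  # combined signal filter falls to half near the measured ~55 Hz corner
  f_sig <- uniroot(function(f) {
    bump_filter_power(f) * latency_filter_power(f) - 0.5
  }, c(10, 200))$root
  expect_gt(f_sig, 50); expect_lt(f_sig, 57)
  # tau_d -> 0 recovers the bump filter alone
  expect_equal(bump_filter_power(60) * latency_filter_power(60, 1e-9, 2),
               bump_filter_power(60), tolerance = 1e-6)
})

test_that("binomial SNR follows the square-root law", {
  expect_equal(binomial_snr(4), 1)
  expect_equal(binomial_snr(230 * 260), 0.5 * sqrt(59800))
  expect_equal(binomial_snr(230 * 260), 122.3, tolerance = 1e-3)
  expect_equal(binomial_snr(4e4), 2 * binomial_snr(1e4))
})

test_that("half-saturation rate is consistent with saturation algebra", {
  expect_equal(half_saturation_rate(60000, 0.1), 3e5)
  expect_equal(half_saturation_rate(0, 0.1), 0)
  # psi = I50 I/(I50 + I) evaluated at I = I50 gives I50/2
  N <- 60000; tau_r <- 0.1
  I50 <- N / tau_r
  expect_equal(I50 * I50 / (I50 + I50), half_saturation_rate(N, tau_r))
  # slope d psi/d I = I50^2/(I50+I)^2 equals 1/4 at half-saturation
  expect_equal(I50^2 / (I50 + I50)^2, 1 / 4)
})

test_that("signal spectrum is the product of its parts", {
  g <- ref_ns_geometry()
  sc <- scene_model(); om <- optical_model("COG")
  prm <- photoreceptor_model()
  psi <- half_saturation_rate(prm$nu * g$L, prm$tau_r)
  drho <- acceptance_angle(om, g$D, g$f, g$d_rh)
  fr <- 12; ft <- 30
  expect_equal(signal_spectrum(fr, ft, g, sc, om, prm),
               (3 * psi)^2 * spatiotemporal_spectrum(fr, ft, sc) *
                 spatial_mtf(fr, drho)^2 * bump_filter_power(ft) *
                 latency_filter_power(ft))
  # zero-length photoreceptors transduce nothing
  g0 <- eye_geometry("NS", D = 25, L = 0, delta_phi = deg_to_rad(1.5))
  expect_equal(signal_spectrum(fr, ft, g0, sc, om, prm), 0)
})

test_that("fused pixels halve transduction: signal 4x, noise 2x below NS", {
  gNS <- ref_ns_geometry()
  gF <- eye_geometry("FUSED", D = 25, L = 200,
                     delta_phi = deg_to_rad(1.5), F = 2, d_rh = 1.9)
  sc <- scene_model(); om <- optical_model("COG")
  prm <- photoreceptor_model()
  expect_equal(signal_spectrum(10, 20, gNS, sc, om, prm) /
                 signal_spectrum(10, 20, gF, sc, om, prm), 4)
  expect_equal(shot_noise_spectrum(20, gNS, prm) /
                 shot_noise_spectrum(20, gF, prm), 2)
})

test_that("shot noise integrates to the pixel noise power over the disc", {
  g <- ref_ns_geometry()
  prm <- photoreceptor_model()
  mu_s <- hexagonal_cutoff(g$delta_phi)
  dens <- shot_noise_spectrum(35, g, prm)
  psi <- half_saturation_rate(prm$nu * g$L, prm$tau_r)
  expect_equal(dens * pi * mu_s^2, 3 * psi * bump_filter_power(35))
})

test_that("aliasing vanishes under heavy blur or dense sampling", {
  sc <- scene_model(); prm <- photoreceptor_model()
  # heavy blur: a huge rhabdomere makes the MTF kill out-of-band power
  g_blur <- eye_geometry("NS", D = 25, L = 200,
                         delta_phi = deg_to_rad(1.5), d_rh = 60)
  g_ref <- ref_ns_geometry()
  om <- optical_model("COG")
  expect_lt(aliasing_spectrum(10, g_blur, sc, om, prm),
            1e-6 * aliasing_spectrum(10, g_ref, sc, om, prm))
  # cutoff at or below the sampling limit leaves nothing to alias
  expect_equal(
    aliasing_spectrum(10, g_ref, sc, om, prm,
                      f_cut = hexagonal_cutoff(g_ref$delta_phi)), 0)
})

test_that("in-band plus aliased spatial power conserves the filtered total", {
  g <- ref_ns_geometry()
  sc <- scene_model(); om <- optical_model("COG")
  drho <- acceptance_angle(om, g$D, g$f, g$d_rh)
  mu_s <- hexagonal_cutoff(g$delta_phi)
  f_cut <- 3 / drho
  ft <- 15
  piece <- function(lo, hi) {
    integrate(function(f) {
      2 * pi * f * spatiotemporal_spectrum(f, ft, sc) *
        spatial_mtf(f, drho)^2
    }, lo, hi, rel.tol = 1e-10)$value
  }
  total <- piece(1e-4 * mu_s, f_cut)
  in_band <- piece(1e-4 * mu_s, mu_s)
  out_band <- eyecost:::aliased_power(ft, mu_s, f_cut, drho, sc)
  expect_equal(in_band + out_band, total, tolerance = 1e-6)
})

test_that("spectra are non-negative and S/N is scale-invariant", {
  g <- ref_ns_geometry()
  sc <- scene_model(); om <- optical_model("COG")
  prm <- photoreceptor_model()
  fr <- c(0.5, 5, 20); ft <- c(0, 40, 300)
  for (t in ft) {
    expect_true(all(signal_spectrum(fr, t, g, sc, om, prm) >= 0))
    expect_gte(shot_noise_spectrum(t, g, prm), 0)
    expect_gte(aliasing_spectrum(t, g, sc, om, prm), 0)
  }
})
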