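test_that("focal distance follows the convex-cornea formula", {
  expect_equal(focal_distance(37, 2, 1.34), 99.16)
  expect_equal(focal_distance(1, 1, 1), 1)
  expect_equal(focal_distance(20, 2, 1.34), 53.6)
  expect_error(focal_distance(-1, 2), "D > 0")
  expect_error(focal_distance(10, 0), "F > 0")
})

test_that("eye radius and eye parameter are consistent inverses", {
  expect_equal(eye_radius(15, deg_to_rad(5.1)), 15 / 0.0890117919,
               tolerance = 1e-8)
  expect_equal(eye_radius(1, 1), 1)
  expect_equal(eye_radius(75, deg_to_rad(0.28)), 75 / deg_to_rad(0.28))
  expect_equal(eye_parameter(75, deg_to_rad(0.28)), 0.37, tolerance = 0.01)
  expect_equal(eye_parameter(1, 1), 1)
  expect_equal(eye_parameter(16.5, deg_to_rad(5)), 1.44, tolerance = 0.01)
  expect_error(eye_radius(10, 0))
})

test_that("diffraction-limit helpers match closed forms", {
  expect_equal(diffraction_limited_p(0.5), 0.5 / sqrt(3))
  expect_equal(diffraction_limited_F(2, 0.5), sqrt(3) * 4)
})

test_that("apposition shell volumes follow the cubic shell formulae", {
  v <- apposition_shell_volumes(1000, 100, 100)
  expect_equal(v$V_o, (1000^3 - 900^3) / 3)   # 9.0333e7
  expect_equal(v$V_ph, (900^3 - 800^3) / 3)   # 7.2333e7
  z <- apposition_shell_volumes(100, 0, 0)
  expect_equal(z$V_o, 0)
  expect_equal(z$V_ph, 0)
  expect_error(apposition_shell_volumes(100, 80, 30), "infeasible")
})

test_that("shell volumes are additive for random feasible geometries", {
  s <- random_shells(1e4)
  v <- apposition_shell_volumes(s$R, s$f_prime, s$L)
  expect_equal(v$V_o + v$V_ph,
               (s$R^3 - (s$R - s$f_prime - s$L)^3) / 3,
               tolerance = 1e-12)
  expect_true(all(v$V_o >= 0) && all(v$V_ph >= 0))
})

test_that("volumes are monotone in radius and array depth", {
  s <- random_shells(500, seed = 99)
  # V_ph strictly increasing in L at fixed R, f'
  v1 <- apposition_shell_volumes(s$R, s$f_prime, s$L * 0.99)
  v2 <- apposition_shell_volumes(s$R, s$f_prime, s$L)
  expect_true(all(v2$V_ph[s$L > 0] > v1$V_ph[s$L > 0]))
  # total cost strictly increasing in R at fixed (D, L, f')
  D <- 20
  c1 <- eyecost:::apposition_cost_at_radius(s$R, D, s$L, s$f_prime, 230,
                                            0.2, 6)
  c2 <- eyecost:::apposition_cost_at_radius(s$R * 1.05, D, s$L, s$f_prime,
                                            230, 0.2, 6)
  expect_true(all(c2 > c1))
})

test_that("simple eye volumes and sampling follow the hemisphere model", {
  v <- simple_eye_volumes(29, 2, 0)
  expect_equal(v$V_o, pi / 3 * 58^3)
  expect_equal(v$V_ph, 0)
  expect_equal(v$V_tot, v$V_o)
  v2 <- simple_eye_volumes(10, 2, 20)
  expect_equal(v2$V_tot, pi / 3 * 40^3)
  expect_equal(v2$V_o + v2$V_ph, v2$V_tot)
  # f-prime convention scales the optics shell by n_i
  v3 <- simple_eye_volumes(10, 2, 0, n_i = 1.34, use_f_prime = TRUE)
  expect_equal(v3$V_o, pi / 3 * (1.34 * 20)^3)
  expect_equal(simple_eye_sampling(29, 2, 1.9), 1.9 / 58)
  expect_equal(simple_eye_sampling(5, 1, 5), 1)
})

test_that("microvillus accounting distinguishes eye types", {
  gNS <- eye_geometry("NS", D = 37, L = 260, delta_phi = deg_to_rad(1.07))
  gF <- eye_geometry("FUSED", D = 37, L = 260,
                     delta_phi = deg_to_rad(1.07), F = 5.5, d_rh = 1.8)
  dens <- pixel_density(deg_to_rad(1.07))
  expect_equal(microvilli_per_steradian(gNS, nu = 230),
               6 * 230 * 260 * dens)
  # per-rhabdomere count ~6e4 cross-checks the published figure
  expect_equal(230 * 260, 59800, tolerance = 0.05)
  # fused pixel carries half the transduction units of an NS pixel
  expect_equal(microvilli_per_steradian(gF, nu = 230) /
                 microvilli_per_steradian(gNS, nu = 230), 0.5)
  g0 <- eye_geometry("NS", D = 37, L = 0, delta_phi = deg_to_rad(1.07))
  expect_equal(microvilli_per_steradian(g0), 0)
})

test_that("energy surcharge is linear in tariff and count", {
  expect_equal(energy_surcharge(0, 1e9), 0)
  expect_equal(energy_surcharge(0.13, 1e9), 1.3e8)
  expect_equal(energy_surcharge(0.13, 2e9), 2 * energy_surcharge(0.13, 1e9))
})

test_that("cost breakdown satisfies its accounting invariants", {
  g <- eye_geometry("NS", D = 15, L = 60, delta_phi = deg_to_rad(5.1),
                    f_prime = 21)
  cb0 <- cost_breakdown(g, K_E = 0)
  expect_equal(cb0$C_tot, cb0$V_tot)            # no surcharge at K_E = 0
  expect_equal(cb0$C_tot, 1.4e6, tolerance = 0.03)  # March fly ventral
  cb <- cost_breakdown(g, K_E = 0.13)
  expect_equal(cb$V_tot, cb$V_o + cb$V_ph)
  expect_equal(cb$C_ph, cb$V_ph + cb$S_E)
  expect_equal(cb$C_tot, cb$C_o + cb$C_ph)
  expect_true(all(unlist(cb) >= 0))
  # dragonfly dorsal fovea total volume
  gS <- eye_geometry("FUSED", D = 71, L = 1107,
                     delta_phi = deg_to_rad(0.35), f_prime = 410)
  expect_equal(cost_breakdown(gS)$V_tot, 1.8e11, tolerance = 0.03)
})

test_that("radius solver inverts the cost constraint", {
  # round trip across random feasible geometries
  set.seed(7)
  for (i in 1:40) {
    D <- runif(1, 8, 120)
    L <- runif(1, 10, 1500)
    K_E <- sample(c(0, 0.13, 0.5), 1)
    f_prime <- focal_distance(D, 2, 1.34)
    R <- (f_prime + L) * (1 + rexp(1, 1))
    g <- eye_geometry("NS", D = D, L = L, R = R)
    ct <- cost_breakdown(g, K_E = K_E)$C_tot
    expect_equal(solve_radius_for_cost(ct, D, L, K_E = K_E), R,
                 tolerance = 1e-8)
  }
  # bisection oracle built on uniroot against the shell volumes
  Fx <- 21 / (1.34 * 15) # reproduce a measured f' = 21 at D = 15
  target <- 1.37e6
  oracle <- uniroot(function(R) {
    v <- apposition_shell_volumes(R, 21, 60)
    v$V_o + v$V_ph - target
  }, c(81, 1e4), tol = 1e-10)$root
  expect_equal(solve_radius_for_cost(target, 15, 60, F = Fx), oracle,
               tolerance = 1e-6)
  expect_equal(oracle, 168.5, tolerance = 1e-3)
  # boundary: budget equal to the minimal-radius cost returns R_min
  D <- 20; L <- 100
  f_prime <- focal_distance(D, 2, 1.34)
  c_min <- eyecost:::apposition_cost_at_radius(f_prime + L, D, L, f_prime,
                                               230, 0, 6)
  expect_equal(solve_radius_for_cost(c_min, D, L), f_prime + L)
  expect_error(solve_radius_for_cost(c_min * 0.9, D, L), "infeasible")
})

test_that("simple-eye length solver inverts its cost constraint", {
  L <- solve_simple_length_for_cost(1e8, 100, K_E = 0.16)
  g <- eye_geometry("SIMPLE", D = 100, L = L)
  expect_equal(cost_breakdown(g, K_E = 0.16)$C_tot, 1e8, tolerance = 1e-8)
  expect_equal(solve_simple_length_for_cost(pi / 3 * 200^3, 100), 0)
  expect_error(solve_simple_length_for_cost(1e3, 100), "infeasible")
})

test_that("eye geometry validates feasibility and derives angles", {
  expect_error(eye_geometry("NS", D = 20, L = 500,
                            delta_phi = deg_to_rad(10)), "infeasible")
  g <- eye_geometry("SIMPLE", D = 29, L = 50)
  expect_equal(g$delta_phi, 1.9 / 58)
  g2 <- eye_geometry("NS", D = 20, L = 50, R = 500)
  expect_equal(g2$delta_phi, 0.04)
})
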