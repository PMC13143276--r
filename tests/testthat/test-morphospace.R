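# Unit-level morphospace checks run on a reduced grid; the full-size
# behavioural checks live in test-acceptance.R.

surf <- performance_surface(1e8, K_E = 0.16, eye_type = "NS",
                            grid_spec = small_grid())

test_that("every feasible surface point meets the cost constraint", {
  g <- surf$grid[surf$grid$feasible, ]
  expect_gt(nrow(g), 10)
  expect_true(all(abs(g$C_tot - 1e8) / 1e8 < 1e-6))
  # recompute one point independently from the stored geometry
  i <- which.max(g$H)
  gg <- eye_geometry("NS", D = g$D[i], L = g$L[i], R = g$R[i])
  cb <- cost_breakdown(gg, K_E = 0.16)
  expect_equal(cb$C_tot, 1e8, tolerance = 1e-6)
  expect_equal(cb$V_o, g$V_o[i], tolerance = 1e-9)
})

test_that("surface bookkeeping: efficiency in [0,1], optimum is argmax", {
  g <- surf$grid[surf$grid$feasible, ]
  expect_true(all(g$efficiency >= 0 & g$efficiency <= 1))
  expect_equal(max(g$efficiency), 1)
  expect_equal(surf$optimum$H, max(g$H))
})

test_that("efficiency-zone thresholds behave at the extremes", {
  z0 <- high_efficiency_zone(surf, 0)
  expect_equal(sum(z0$mask), sum(surf$grid$feasible))
  z1 <- high_efficiency_zone(surf, 1)
  expect_equal(sum(z1$mask), 1)
  expect_true(z1$mask[which(surf$grid$feasible)[
    which.max(surf$grid$H[surf$grid$feasible])] == seq_len(nrow(surf$grid))] ||
      sum(z1$mask) == 1)
})

test_that("refined optimum beats or matches a finer grid argmax", {
  opt <- optimise_eye(1e8, K_E = 0.16, eye_type = "NS",
                      grid_spec = small_grid())
  fine <- performance_surface(1e8, K_E = 0.16, eye_type = "NS",
                              grid_spec = morphospace_grid(
                                D_range = c(8, 150), L_range = c(30, 3000),
                                nD = 30, nL = 30))
  expect_gte(opt$H * (1 + 1e-9), fine$optimum$H * 0.99)
  expect_equal(opt$H, fine$optimum$H, tolerance = 0.01)
  # optimum carries a consistent cost decomposition
  expect_equal(opt$C_tot, 1e8, tolerance = 1e-6)
  expect_equal(opt$pct_Cph + 100 * opt$V_o / opt$C_tot, 100,
               tolerance = 1e-6)
})

test_that("optimisation is deterministic", {
  o1 <- optimise_eye(1e8, K_E = 0.16, eye_type = "NS",
                     grid_spec = small_grid())
  o2 <- optimise_eye(1e8, K_E = 0.16, eye_type = "NS",
                     grid_spec = small_grid())
  expect_identical(o1, o2)
})

test_that("simple-eye morphospace solves L from the budget at each D", {
  s <- performance_surface(1e8, K_E = 0.04, eye_type = "SIMPLE",
                           grid_spec = morphospace_grid(nD = 25))
  g <- s$grid[s$grid$feasible, ]
  expect_true(all(abs(g$C_tot - 1e8) / 1e8 < 1e-6))
  # L falls as D (and hence the optics shell) grows
  expect_true(all(diff(g$L) < 0))
})

test_that("sweeps record failures and keep going", {
  sw <- sweep_total_cost(c(1e3, 1e8), 0.16, eye_type = "NS",
                         grid_spec = small_grid())
  expect_equal(nrow(sw), 2)
  expect_true(is.na(sw$H_opt[sw$C_tot == 1e3]))  # budget below any geometry
  expect_true(is.finite(sw$H_opt[sw$C_tot == 1e8]))
})

test_that("empty feasible sets raise a named error", {
  expect_error(performance_surface(1e3, eye_type = "NS",
                                   grid_spec = small_grid()),
               "feasible")
})

test_that("scaling exponent recovers exact power laws", {
  d <- data.frame(C_tot = 10^(6:10), K_E = 0)
  d$H_opt <- d$C_tot^0.8
  expect_equal(scaling_exponent(d)$slope, 0.8, tolerance = 1e-10)
  d$H_opt <- 7.3 * d$C_tot^0.8   # invariant under rescaling
  expect_equal(scaling_exponent(d)$slope, 0.8, tolerance = 1e-10)
  expect_equal(scaling_exponent(d)$local_slopes, rep(0.8, 4),
               tolerance = 1e-10)
  expect_error(scaling_exponent(d[1:2, ]), "at least 3")
})
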