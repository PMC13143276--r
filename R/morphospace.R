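#' Generic model parameters per eye type
#'
#' Blowfly-derived defaults for the neural-superposition model (`F = 2`,
#' `n_i = 1.34`, `d_rh = 1.9` µm, `nu = 230` µm⁻¹); the fused-rhabdom model
#' uses `F = 5.5` and `d_rh = 1.8` µm (mid-range of the published
#' measurements); the simple-eye model shares the NS optics.
#'
#' @param eye_type `"NS"`, `"FUSED"` or `"SIMPLE"`.
#' @param ... overrides for `F`, `n_i`, `d_rh`, `nu`.
#' @return list with `F`, `n_i`, `d_rh`, `nu`.
#' @export
eye_model_params <- function(eye_type = c("NS", "FUSED", "SIMPLE"), ...) {
  eye_type <- match.arg(eye_type)
  p <- switch(eye_type,
    NS = list(F = 2, n_i = 1.34, d_rh = 1.9, nu = 230),
    FUSED = list(F = 5.5, n_i = 1.34, d_rh = 1.8, nu = 230),
    SIMPLE = list(F = 2, n_i = 1.34, d_rh = 1.9, nu = 230))
  modifyList(p, list(...))
}

#' Morphospace grid specification
#'
#' Log-spaced grid over lens diameter and rhabdom(ere) length. Defaults:
#' 60 x 60 over `D` in 5-500 µm (5-5000 µm for simple eyes, whose optima
#' reach millimetre lenses) and `L` in 5-5000 µm; infeasible pairs are
#' marked, not dropped. For simple eyes `L` is solved from the cost
#' constraint, so only the `D` axis is used.
#'
#' @param D_range,L_range axis limits, micrometres (`NULL` = per-type
#'   default).
#' @param nD,nL nodes per axis.
#' @return list of class `morphospace_grid`.
#' @export
morphospace_grid <- function(D_range = NULL, L_range = c(5, 5000),
                             nD = 60, nL = 60) {
  structure(list(D_range = D_range, L_range = L_range, nD = nD, nL = nL),
            class = "morphospace_grid")
}

logspace <- function(lim, n) exp(seq(log(lim[1]), log(lim[2]), length.out = n))

# Evaluate one apposition morphospace point at fixed budget; returns a row.
apposition_point <- function(D, L, C_tot, K_E, eye_type, params, scene,
                             optics, prm, control) {
  f_prime <- focal_distance(D, params$F, params$n_i)
  q <- rhabdomere_equivalents(eye_type)
  R_min <- f_prime + L
  c_min <- apposition_cost_at_radius(R_min, D, L, f_prime, params$nu, K_E, q)
  if (C_tot < c_min * (1 - 1e-12)) return(NULL)
  R <- solve_radius_for_cost(C_tot, D, L, eye_type = eye_type,
                             F = params$F, n_i = params$n_i,
                             d_rh = params$d_rh, nu = params$nu, K_E = K_E)
  geom <- eye_geometry(eye_type, D = D, L = L, R = R, F = params$F,
                       n_i = params$n_i, d_rh = params$d_rh)
  cb <- cost_breakdown(geom, nu = params$nu, K_E = K_E)
  H <- capacity_core(geom, scene, optics, prm, control)$H
  c(R = R, delta_phi = geom$delta_phi, V_o = cb$V_o, V_ph = cb$V_ph,
    S_E = cb$S_E, C_ph = cb$C_ph, C_tot = cb$C_tot, H = H)
}

simple_point <- function(D, C_tot, K_E, params, scene, optics, prm,
                         control) {
  c_min <- pi / 3 * (D * params$F)^3
  if (C_tot < c_min * (1 - 1e-12)) return(NULL)
  L <- solve_simple_length_for_cost(C_tot, D, F = params$F,
                                    n_i = params$n_i, d_rh = params$d_rh,
                                    nu = params$nu, K_E = K_E)
  geom <- eye_geometry("SIMPLE", D = D, L = L, F = params$F,
                       n_i = params$n_i, d_rh = params$d_rh)
  cb <- cost_breakdown(geom, nu = params$nu, K_E = K_E)
  H <- capacity_core(geom, scene, optics, prm, control)$H
  c(L = L, delta_phi = geom$delta_phi, V_o = cb$V_o, V_ph = cb$V_ph,
    S_E = cb$S_E, C_ph = cb$C_ph, C_tot = cb$C_tot, H = H)
}

#' Fixed-cost performance surface H(D, L)
#'
#' Covers the morphospace of an eye of given type and total cost: for each
#' grid pair `(D, L)` the cost constraint is inverted for the local radius
#' (apposition) or the rhabdom length is solved from the budget at each
#' `D` (simple eyes, a 1-D morphospace in the same interface), and the
#' information capacity of the resulting geometry is computed. Infeasible
#' pairs are retained with `feasible = FALSE`.
#'
#' @param C_tot total-cost budget, µm³ sr⁻¹.
#' @param K_E photoreceptor energy tariff, µm³ per microvillus.
#' @param eye_type `"NS"`, `"FUSED"` or `"SIMPLE"`.
#' @param optics_mode `"COG"` or `"WOM"`.
#' @param grid_spec a [morphospace_grid()].
#' @param params an [eye_model_params()] list.
#' @param scene,prm,control model components; `prm` defaults to a
#'   [photoreceptor_model()] carrying `params$nu`.
#' @param lambda wavelength, micrometres.
#' @return object of class `performance_surface`: the point grid (a
#'   data.frame with geometry, cost decomposition, `H` and `efficiency =
#'   H/H_max`), the argmax `optimum`, and the configuration.
#' @export
performance_surface <- function(C_tot, K_E = 0,
                                eye_type = c("NS", "FUSED", "SIMPLE"),
                                optics_mode = c("COG", "WOM"),
                                grid_spec = morphospace_grid(),
                                params = eye_model_params(eye_type),
                                scene = scene_model(),
                                prm = photoreceptor_model(nu = params$nu),
                                control = capacity_control(),
                                lambda = 0.5) {
  eye_type <- match.arg(eye_type)
  optics_mode <- match.arg(optics_mode)
  stopifnot(C_tot > 0, K_E >= 0)
  optics <- optical_model(optics_mode, lambda = lambda)
  D_range <- grid_spec$D_range
  if (is.null(D_range)) {
    D_range <- if (eye_type == "SIMPLE") c(5, 5000) else c(5, 500)
  }
  Ds <- logspace(D_range, grid_spec$nD)
  if (eye_type == "SIMPLE") {
    rows <- lapply(Ds, function(D) {
      p <- simple_point(D, C_tot, K_E, params, scene, optics, prm, control)
      if (is.null(p)) {
        data.frame(D = D, L = NA_real_, R = NA_real_, delta_phi = NA_real_,
                   V_o = NA_real_, V_ph = NA_real_, S_E = NA_real_,
                   C_ph = NA_real_, C_tot = NA_real_, H = NA_real_,
                   feasible = FALSE)
      } else {
        data.frame(D = D, L = p[["L"]], R = NA_real_,
                   delta_phi = p[["delta_phi"]], V_o = p[["V_o"]],
                   V_ph = p[["V_ph"]], S_E = p[["S_E"]], C_ph = p[["C_ph"]],
                   C_tot = p[["C_tot"]], H = p[["H"]], feasible = TRUE)
      }
    })
    grid <- do.call(rbind, rows)
    dims <- c(grid_spec$nD, 1L)
  } else {
    Ls <- logspace(grid_spec$L_range, grid_spec$nL)
    combos <- expand.grid(L = Ls, D = Ds)[, c("D", "L")]
    rows <- mapply(function(D, L) {
      p <- apposition_point(D, L, C_tot, K_E, eye_type, params, scene,
                            optics, prm, control)
      if (is.null(p)) c(R = NA_real_, delta_phi = NA_real_, V_o = NA_real_,
                        V_ph = NA_real_, S_E = NA_real_, C_ph = NA_real_,
                        C_tot = NA_real_, H = NA_real_)
      else p
    }, combos$D, combos$L)
    grid <- cbind(combos, as.data.frame(t(rows)))
    grid$feasible <- is.finite(grid$H)
    dims <- c(grid_spec$nD, grid_spec$nL)
  }
  H_max <- suppressWarnings(max(grid$H, na.rm = TRUE))
  if (!is.finite(H_max)) {
    stop(sprintf(
      "empty feasible set: no (D, L) pair attains cost %.4g within the grid",
      C_tot))
  }
  grid$efficiency <- grid$H / H_max
  opt <- grid[pick_optimum(grid), , drop = FALSE]
  structure(list(grid = grid, optimum = opt, dims = dims,
                 C_tot = C_tot, K_E = K_E, eye_type = eye_type,
                 optics_mode = optics_mode, params = params,
                 D_values = Ds,
                 L_values = if (eye_type == "SIMPLE") NULL else Ls),
            class = "performance_surface")
}

# Argmax row index with deterministic tie-breaking: smaller L, then
# smaller D (cheaper photoreceptors preferred on exact plateaus).
pick_optimum <- function(grid) {
  H <- ifelse(grid$feasible, grid$H, -Inf)
  best <- which(H == max(H))
  if (length(best) > 1) {
    best <- best[order(grid$L[best], grid$D[best])][1]
  }
  best
}

#' @export
print.performance_surface <- function(x, ...) {
  cat(sprintf(
    "<performance_surface> %s eye, %s optics, C_tot = %.3g, K_E = %.2g\n",
    x$eye_type, x$optics_mode, x$C_tot, x$K_E))
  cat(sprintf("  %d/%d feasible points; optimum H = %.5g at D = %.3g um, L = %.3g um\n",
              sum(x$grid$feasible), nrow(x$grid), x$optimum$H,
              x$optimum$D, x$optimum$L))
  invisible(x)
}

#' High-efficiency zone of a performance surface
#'
#' @param surface a [performance_surface()].
#' @param threshold efficiency threshold (default 0.95).
#' @return list: logical `mask` over the grid rows, `fraction` of feasible
#'   morphospace inside the zone, fold-`extent` of `D` and `L` across the
#'   zone, and `n_components` (connected components on the grid lattice;
#'   1 means the zone is connected).
#' @export
high_efficiency_zone <- function(surface, threshold = 0.95) {
  stopifnot(inherits(surface, "performance_surface"),
            threshold >= 0, threshold <= 1)
  g <- surface$grid
  mask <- g$feasible & !is.na(g$efficiency) & g$efficiency >= threshold
  zone <- g[mask, , drop = FALSE]
  extent <- function(v) if (nrow(zone)) max(v) / min(v) else NA_real_
  list(mask = mask,
       fraction = sum(mask) / max(sum(g$feasible), 1L),
       D_extent = extent(zone$D),
       L_extent = if (all(is.na(zone$L))) NA_real_ else extent(zone$L),
       n_components = count_components(mask, surface$dims))
}

# Connected components of a logical mask laid out column-major as
# (nL rows within each D) x nD, 4-neighbour connectivity.
count_components <- function(mask, dims) {
  nD <- dims[1]; nL <- dims[2]
  m <- matrix(mask, nrow = nL, ncol = nD)
  lab <- matrix(0L, nL, nD)
  comp <- 0L
  for (j in seq_len(nD)) for (i in seq_len(nL)) {
    if (m[i, j] && lab[i, j] == 0L) {
      comp <- comp + 1L
      queue <- list(c(i, j))
      lab[i, j] <- comp
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          a <- cur[1] + d[1]; b <- cur[2] + d[2]
          if (a >= 1 && a <= nL && b >= 1 && b <= nD &&
              m[a, b] && lab[a, b] == 0L) {
            lab[a, b] <- comp
            queue[[length(queue) + 1]] <- c(a, b)
          }
        }
      }
    }
  }
  comp
}

#' Optimal eye configuration at fixed cost
#'
#' Grid argmax of the performance surface, refined by deterministic local
#' search (Nelder-Mead over `(log D, log L)` for apposition eyes; 1-D
#' golden-section over `log D` for simple eyes). Ties on the flat ridge
#' break toward smaller `L`, then smaller `D`.
#'
#' @inheritParams performance_surface
#' @param surface optionally a precomputed [performance_surface()] for the
#'   same configuration (skips the grid pass).
#' @param refine logical; run the local search (default `TRUE`).
#' @return one-row data.frame (a morphospace point): geometry, cost
#'   decomposition, `H`, plus `p` (eye parameter) and allocation
#'   percentages `pct_Cph`, `pct_SE`.
#' @export
optimise_eye <- function(C_tot, K_E = 0,
                         eye_type = c("NS", "FUSED", "SIMPLE"),
                         optics_mode = c("COG", "WOM"),
                         grid_spec = morphospace_grid(),
                         params = eye_model_params(eye_type),
                         scene = scene_model(),
                         prm = photoreceptor_model(nu = params$nu),
                         control = capacity_control(),
                         lambda = 0.5, surface = NULL, refine = TRUE) {
  eye_type <- match.arg(eye_type)
  optics_mode <- match.arg(optics_mode)
  if (is.null(surface)) {
    surface <- performance_surface(C_tot, K_E, eye_type, optics_mode,
                                   grid_spec, params, scene, prm, control,
                                   lambda)
  }
  optics <- optical_model(optics_mode, lambda = lambda)
  opt <- surface$optimum
  if (refine) {
    if (eye_type == "SIMPLE") {
      obj <- function(logD) {
        p <- simple_point(exp(logD), C_tot, K_E, params, scene, optics,
                          prm, control)
        if (is.null(p)) -1e300 else p[["H"]]
      }
      Ds <- surface$D_values
      i <- which(Ds == opt$D)[1]
      lo <- log(Ds[max(1, i - 1)]); hi <- log(Ds[min(length(Ds), i + 1)])
      o <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
      if (o$objective > opt$H) {
        p <- simple_point(exp(o$maximum), C_tot, K_E, params, scene,
                          optics, prm, control)
        opt <- data.frame(D = exp(o$maximum), L = p[["L"]], R = NA_real_,
                          delta_phi = p[["delta_phi"]], V_o = p[["V_o"]],
                          V_ph = p[["V_ph"]], S_E = p[["S_E"]],
                          C_ph = p[["C_ph"]], C_tot = p[["C_tot"]],
                          H = p[["H"]], feasible = TRUE,
                          efficiency = NA_real_)
      }
    } else {
      obj <- function(x) {
        p <- tryCatch(
          apposition_point(exp(x[1]), exp(x[2]), C_tot, K_E, eye_type,
                           params, scene, optics, prm, control),
          error = function(e) NULL)
        if (is.null(p)) 1e300 else -p[["H"]]
      }
      o <- optim(c(log(opt$D), log(opt$L)), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-7, maxit = 300))
      if (-o$value > opt$H) {
        D <- exp(o$par[1]); L <- exp(o$par[2])
        p <- apposition_point(D, L, C_tot, K_E, eye_type, params, scene,
                              optics, prm, control)
        opt <- data.frame(D = D, L = L, R = p[["R"]],
                          delta_phi = p[["delta_phi"]], V_o = p[["V_o"]],
                          V_ph = p[["V_ph"]], S_E = p[["S_E"]],
                          C_ph = p[["C_ph"]], C_tot = p[["C_tot"]],
                          H = p[["H"]], feasible = TRUE,
                          efficiency = NA_real_)
      }
    }
  }
  opt$p <- opt$D * opt$delta_phi
  opt$pct_Cph <- 100 * opt$C_ph / opt$C_tot
  opt$pct_SE <- 100 * opt$S_E / opt$C_tot
  opt$Vph_frac <- opt$V_ph / (opt$V_o + opt$V_ph)
  rownames(opt) <- NULL
  opt
}

#' Sweep optima across total costs and energy tariffs
#'
#' Optimises the eye at every combination of budget and tariff and records
#' the optimum structure, performance and resource division. Failures at
#' individual combinations are recorded as `NA` rows and the sweep
#' continues.
#'
#' @param C_tot_values budgets, µm³ sr⁻¹ (non-empty).
#' @param K_E_values tariffs, µm³ per microvillus (non-empty).
#' @inheritParams optimise_eye
#' @return data.frame of class `sweep_result`: one row per combination
#'   with `C_tot`, `K_E`, `D_opt`, `L_opt`, `dphi_opt_deg`, `p_opt`,
#'   `H_opt`, `pct_Cph`, `pct_SE`, `Vph_frac`.
#' @export
sweep_total_cost <- function(C_tot_values, K_E_values = 0,
                             eye_type = c("NS", "FUSED", "SIMPLE"),
                             optics_mode = c("COG", "WOM"),
                             grid_spec = morphospace_grid(),
                             params = eye_model_params(eye_type),
                             scene = scene_model(),
                             prm = photoreceptor_model(nu = params$nu),
                             control = capacity_control(),
                             lambda = 0.5, refine = TRUE) {
  eye_type <- match.arg(eye_type)
  optics_mode <- match.arg(optics_mode)
  stopifnot(length(C_tot_values) > 0, length(K_E_values) > 0)
  combos <- expand.grid(C_tot = C_tot_values, K_E = K_E_values)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ct <- combos$C_tot[i]; ke <- combos$K_E[i]
    opt <- tryCatch(
      optimise_eye(ct, ke, eye_type, optics_mode, grid_spec, params,
                   scene, prm, control, lambda, refine = refine),
      error = function(e) NULL)
    if (is.null(opt)) {
      data.frame(C_tot = ct, K_E = ke, D_opt = NA_real_, L_opt = NA_real_,
                 dphi_opt_deg = NA_real_, p_opt = NA_real_,
                 H_opt = NA_real_, pct_Cph = NA_real_, pct_SE = NA_real_,
                 Vph_frac = NA_real_)
    } else {
      data.frame(C_tot = ct, K_E = ke, D_opt = opt$D, L_opt = opt$L,
                 dphi_opt_deg = rad_to_deg(opt$delta_phi), p_opt = opt$p,
                 H_opt = opt$H, pct_Cph = opt$pct_Cph,
                 pct_SE = opt$pct_SE, Vph_frac = opt$Vph_frac)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Log-log scaling exponent along a sweep
#'
#' Ordinary least-squares slope of `log10(quantity)` against
#' `log10(C_tot)` over the rows of a sweep (optionally restricted to one
#' tariff), plus piecewise local slopes between consecutive budgets.
#'
#' @param sweep a [sweep_total_cost()] result (or any data.frame with a
#'   `C_tot` column).
#' @param quantity column name to regress (default `"H_opt"`).
#' @param K_E restrict to rows at this tariff (default: all rows).
#' @return list with `slope`, `local_slopes`, `n`.
#' @export
scaling_exponent <- function(sweep, quantity = "H_opt", K_E = NULL) {
  stopifnot(is.data.frame(sweep), quantity %in% names(sweep))
  d <- sweep
  if (!is.null(K_E)) d <- d[d$K_E == K_E, , drop = FALSE]
  d <- d[is.finite(d[[quantity]]) & is.finite(d$C_tot), , drop = FALSE]
  d <- d[order(d$C_tot), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 sweep points to fit a slope")
  x <- log10(d$C_tot); y <- log10(d[[quantity]])
  list(slope = unname(coef(lm(y ~ x))[2]),
       local_slopes = diff(y) / diff(x),
       n = nrow(d))
}
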