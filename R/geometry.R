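#' Convert between degrees and radians
#'
#' Angles are stored in radians internally; published tables print degrees,
#' so these helpers sit at every I/O boundary.
#'
#' @param deg,rad angle in degrees / radians.
#' @return numeric angle in the other unit.
#' @export
deg_to_rad <- function(deg) deg * pi / 180

#' @rdname deg_to_rad
#' @export
rad_to_deg <- function(rad) rad * 180 / pi

#' Focal distance of a convex-cornea eye
#'
#' Image formation by a convex cornea places the focal plane at
#' `f' = F * n_i * D`, where `F = f/D` is the F-number and `n_i` the
#' refractive index of the eye's internal medium.
#'
#' @param D lens diameter, micrometres.
#' @param F F-number (focal length in air over aperture), dimensionless.
#' @param n_i internal refractive index (>= 1).
#' @return focal distance in micrometres.
#' @examples
#' focal_distance(37, 2, 1.34) # 99.16, blowfly male acute zone
#' @export
focal_distance <- function(D, F, n_i = 1.34) {
  stopifnot(all(D > 0), all(F > 0), all(n_i >= 1))
  F * n_i * D
}

#' Local radius of a spherical apposition eye region
#'
#' @param D lens diameter, micrometres.
#' @param delta_phi interommatidial angle, radians.
#' @return eye radius `R = D / delta_phi`, micrometres.
#' @export
eye_radius <- function(D, delta_phi) {
  stopifnot(all(D > 0), all(delta_phi > 0))
  D / delta_phi
}

#' Eye parameter
#'
#' The product `p = D * delta_phi` (micrometre-radians) indexes how far an
#' eye samples above the diffraction limit; diffraction-limited hexagonal
#' sampling corresponds to `p = lambda / sqrt(3)`.
#'
#' @param D lens diameter, micrometres.
#' @param delta_phi interommatidial angle, radians.
#' @return eye parameter, micrometre-radians.
#' @seealso [diffraction_limited_p()]
#' @export
eye_parameter <- function(D, delta_phi) {
  stopifnot(all(D > 0), all(delta_phi > 0))
  D * delta_phi
}

#' Diffraction-limited eye parameter for a hexagonal array
#'
#' Setting the hexagonal sampling cutoff `1/(sqrt(3) delta_phi)` equal to
#' the lens diffraction cutoff `D / lambda` gives `p = lambda / sqrt(3)`.
#'
#' @param lambda wavelength of light, micrometres (default 0.5).
#' @return eye parameter at the diffraction limit, micrometre-radians.
#' @export
diffraction_limited_p <- function(lambda = 0.5) {
  stopifnot(lambda > 0)
  lambda / sqrt(3)
}

#' F-number at which a simple eye reaches the diffraction limit
#'
#' For a hexagonal mosaic of photoreceptors of entrance-aperture diameter
#' `d_rh`, the lens diffraction limit `lambda/D` matches the mosaic limit
#' `sqrt(3) d_rh / (D F)` when `F = sqrt(3) d_rh / lambda`.
#'
#' @param d_rh rhabdom diameter, micrometres (default 2).
#' @param lambda wavelength, micrometres (default 0.5).
#' @return F-number, dimensionless.
#' @export
diffraction_limited_F <- function(d_rh = 2, lambda = 0.5) {
  stopifnot(d_rh > 0, lambda > 0)
  sqrt(3) * d_rh / lambda
}

#' Specific volumes of an apposition eye region
#'
#' In a locally spherical eye region of radius `R`, the dioptric apparatus
#' is a shell of thickness `f'` and the photoreceptor array the shell of
#' thickness `L` beneath it:
#' \deqn{V_o = [R^3 - (R - f')^3]/3, \quad
#'       V_{ph} = [(R - f')^3 - (R - f' - L)^3]/3}
#' in µm³ per steradian.
#'
#' @param R local eye radius, micrometres.
#' @param f_prime focal distance (shell thickness of the optics), micrometres.
#' @param L depth of the photoreceptor array, micrometres.
#' @return list with components `V_o` and `V_ph` (µm³ sr⁻¹).
#' @export
apposition_shell_volumes <- function(R, f_prime, L) {
  stopifnot(all(f_prime >= 0), all(L >= 0))
  if (any(R < f_prime + L - 1e-9 * R)) {
    stop("infeasible geometry: R < f' + L (optics and array do not fit inside the eye)")
  }
  inner <- R - f_prime
  list(
    V_o = (R^3 - inner^3) / 3,
    V_ph = (inner^3 - (inner - L)^3) / 3
  )
}

#' Specific volumes of a hemispherical simple eye
#'
#' The optics of a hemispherical simple eye occupy `V_o = (pi/3) f^3` with
#' `f = D F`, and a photoreceptor layer of depth `L` brings the total to
#' `V_tot = (pi/3) (D F + L)^3`. Setting `use_f_prime = TRUE` replaces the
#' focal length in air `f = D F` by the focal distance `f' = F n_i D`
#' throughout (the two conventions differ by the factor `n_i`).
#'
#' @param D lens diameter, micrometres.
#' @param F F-number.
#' @param L rhabdom length, micrometres.
#' @param n_i internal refractive index, used only when `use_f_prime = TRUE`.
#' @param use_f_prime logical; measure the optics shell by focal distance
#'   rather than focal length in air. Default `FALSE`.
#' @return list with components `V_o`, `V_ph`, `V_tot` (µm³ sr⁻¹).
#' @export
simple_eye_volumes <- function(D, F, L, n_i = 1.34, use_f_prime = FALSE) {
  stopifnot(all(D > 0), all(F > 0), all(L >= 0))
  f <- if (use_f_prime) F * n_i * D else D * F
  V_o <- pi / 3 * f^3
  V_tot <- pi / 3 * (f + L)^3
  list(V_o = V_o, V_ph = V_tot - V_o, V_tot = V_tot)
}

#' Interreceptor angle of a simple eye
#'
#' Receptor spacing in a simple eye is the angular subtense of one
#' rhabdom at the nodal point: `delta_phi = d_rh / (D F)`.
#'
#' @param D lens diameter, micrometres.
#' @param F F-number.
#' @param d_rh rhabdom diameter, micrometres.
#' @return interreceptor angle, radians.
#' @export
simple_eye_sampling <- function(D, F, d_rh) {
  stopifnot(all(D > 0), all(F > 0), all(d_rh > 0))
  d_rh / (D * F)
}

#' Ommatidial (pixel) density of a hexagonal lattice
#'
#' A hexagonal lattice with angular pitch `delta_phi` packs
#' `2 sqrt(3) / (3 delta_phi^2)` sampling units per steradian.
#'
#' @param delta_phi angular pitch, radians.
#' @return pixels per steradian.
#' @export
pixel_density <- function(delta_phi) {
  stopifnot(all(delta_phi > 0))
  2 * sqrt(3) / (3 * delta_phi^2)
}

# Rhabdomere-equivalents contributing microvilli to one pixel.
# NS: six photoreceptors, one rhabdomere each. Fused/simple: a triradiate
# rhabdom equivalent to three fly R1-6 rhabdomeres.
rhabdomere_equivalents <- function(eye_type) {
  switch(eye_type, NS = 6, FUSED = 3, SIMPLE = 3,
         stop("unknown eye_type: ", eye_type))
}

#' Construct the dimensioned description of one eye region
#'
#' Bundles the geometry of a locally spherical apposition eye region (or a
#' hemispherical simple eye) and validates feasibility. For apposition eyes
#' supply either `delta_phi` or `R` (the other is derived via
#' `R = D / delta_phi`); for simple eyes `delta_phi = d_rh / (D F)` is
#' implied. The focal distance defaults to `F * n_i * D` unless a measured
#' `f_prime` is given.
#'
#' @param eye_type one of `"NS"` (neural superposition), `"FUSED"`
#'   (fused-rhabdom apposition), `"SIMPLE"`.
#' @param D lens diameter, micrometres.
#' @param L rhabdom(ere) length / array depth, micrometres.
#' @param delta_phi interommatidial angle, radians (apposition only).
#' @param R local eye radius, micrometres (alternative to `delta_phi`).
#' @param F F-number. @param n_i internal refractive index.
#' @param d_rh rhabdom(ere) diameter, micrometres.
#' @param f_prime measured focal distance, micrometres (optional).
#' @return object of class `eye_geometry`.
#' @examples
#' eye_geometry("NS", D = 16.5, L = 83, delta_phi = deg_to_rad(5),
#'              f_prime = 27)
#' @export
eye_geometry <- function(eye_type = c("NS", "FUSED", "SIMPLE"),
                         D, L, delta_phi = NULL, R = NULL,
                         F = 2, n_i = 1.34, d_rh = 1.9, f_prime = NULL) {
  eye_type <- match.arg(eye_type)
  stopifnot(D > 0, L >= 0, F > 0, n_i >= 1, d_rh > 0)
  f <- D * F
  if (is.null(f_prime)) f_prime <- focal_distance(D, F, n_i)
  if (eye_type == "SIMPLE") {
    delta_phi <- simple_eye_sampling(D, F, d_rh)
    R <- NA_real_
  } else {
    if (is.null(delta_phi) && is.null(R)) {
      stop("apposition eyes need delta_phi or R")
    }
    if (is.null(R)) R <- eye_radius(D, delta_phi)
    if (is.null(delta_phi)) delta_phi <- D / R
    stopifnot(delta_phi > 0)
    if (R < f_prime + L - 1e-9 * R) {
      stop(sprintf(
        "infeasible geometry: R = %.4g < f' + L = %.4g", R, f_prime + L))
    }
  }
  structure(
    list(eye_type = eye_type, D = D, L = L, delta_phi = delta_phi, R = R,
         F = F, n_i = n_i, d_rh = d_rh, f = f, f_prime = f_prime),
    class = "eye_geometry")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf("<eye_geometry> %s: D = %.3g um, L = %.3g um, dphi = %.3g deg",
              x$eye_type, x$D, x$L, rad_to_deg(x$delta_phi)))
  if (is.finite(x$R)) cat(sprintf(", R = %.4g um", x$R))
  cat(sprintf(", f' = %.3g um\n", x$f_prime))
  invisible(x)
}

#' Microvilli per steradian of visual field
#'
#' One pixel is served by `rhabdomere-equivalents x nu x L` microvilli
#' (six rhabdomere-equivalents in an NS eye, three in fused-rhabdom and
#' simple eyes) and a hexagonal lattice packs [pixel_density()] pixels per
#' steradian.
#'
#' @param geom an [eye_geometry()].
#' @param nu microvilli per micrometre of rhabdomere (default 230).
#' @param equivalents override the per-pixel rhabdomere-equivalent count.
#' @return microvilli per steradian.
#' @export
microvilli_per_steradian <- function(geom, nu = 230, equivalents = NULL) {
  stopifnot(inherits(geom, "eye_geometry"), nu > 0)
  if (is.null(equivalents)) equivalents <- rhabdomere_equivalents(geom$eye_type)
  equivalents * nu * geom$L * pixel_density(geom$delta_phi)
}

#' Photoreceptor energy surcharge
#'
#' The energy consumed by phototransduction is converted into an equivalent
#' eye volume: `S_E = K_E * N_vil` µm³ sr⁻¹, with `K_E` the energy tariff
#' (µm³ per microvillus) and `N_vil` counted per steradian.
#'
#' @param K_E energy tariff, µm³ per microvillus.
#' @param N_vil_sr microvilli per steradian.
#' @return surcharge, µm³ sr⁻¹.
#' @export
energy_surcharge <- function(K_E, N_vil_sr) {
  stopifnot(all(K_E >= 0), all(N_vil_sr >= 0))
  K_E * N_vil_sr
}

#' Cost breakdown of one eye region
#'
#' Assembles specific volumes and costs: `C_o = V_o`,
#' `C_ph = V_ph + S_E`, `C_tot = C_o + C_ph`, dispatching on eye type
#' (spherical shells for apposition eyes, hemispheres for simple eyes).
#'
#' @inheritParams microvilli_per_steradian
#' @param K_E photoreceptor energy tariff, µm³ per microvillus.
#' @param use_f_prime simple eyes only; see [simple_eye_volumes()].
#' @return object of class `cost_breakdown`: a list with `V_o`, `V_ph`,
#'   `V_tot`, `S_E`, `C_o`, `C_ph`, `C_tot`, `N_vil_sr` (all per steradian).
#' @examples
#' g <- eye_geometry("NS", D = 15, L = 60, delta_phi = deg_to_rad(5.1),
#'                   f_prime = 21)
#' cost_breakdown(g)$C_tot # ~1.4e6 um^3/sr, March fly ventral eye
#' @export
cost_breakdown <- function(geom, nu = 230, K_E = 0, equivalents = NULL,
                           use_f_prime = FALSE) {
  stopifnot(inherits(geom, "eye_geometry"))
  if (geom$eye_type == "SIMPLE") {
    v <- simple_eye_volumes(geom$D, geom$F, geom$L, n_i = geom$n_i,
                            use_f_prime = use_f_prime)
    V_o <- v$V_o; V_ph <- v$V_ph
  } else {
    v <- apposition_shell_volumes(geom$R, geom$f_prime, geom$L)
    V_o <- v$V_o; V_ph <- v$V_ph
  }
  N_vil_sr <- microvilli_per_steradian(geom, nu = nu, equivalents = equivalents)
  S_E <- energy_surcharge(K_E, N_vil_sr)
  structure(
    list(V_o = V_o, V_ph = V_ph, V_tot = V_o + V_ph,
         S_E = S_E, C_o = V_o, C_ph = V_ph + S_E,
         C_tot = V_o + V_ph + S_E, N_vil_sr = N_vil_sr),
    class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "<cost_breakdown> V_o = %.4g, V_ph = %.4g, S_E = %.4g um^3/sr\n",
    x$V_o, x$V_ph, x$S_E))
  cat(sprintf("  C_tot = %.4g um^3/sr (%.1f%% photoreceptor array)\n",
              x$C_tot, 100 * x$C_ph / x$C_tot))
  invisible(x)
}

# Total cost of an apposition region as a function of R at fixed (D, L).
# Strictly increasing in R: shells thicken and pixels densify together.
apposition_cost_at_radius <- function(R, D, L, f_prime, nu, K_E, equivalents) {
  inner <- R - f_prime
  V <- (R^3 - (inner - L)^3) / 3
  N <- equivalents * nu * L * pixel_density(D / R)
  V + K_E * N
}

#' Invert the cost constraint for an apposition eye
#'
#' Given a total-cost budget and a `(D, L)` pair, finds the unique local
#' eye radius `R` at which the region's total cost equals the budget.
#' Total cost is strictly increasing in `R` at fixed `(D, L)`, so bisection
#' between the minimal feasible radius `R = f' + L` and a geometrically
#' grown upper bracket converges unconditionally.
#'
#' @param C_tot total-cost budget, µm³ sr⁻¹.
#' @param D lens diameter, micrometres. @param L array depth, micrometres.
#' @param eye_type `"NS"` or `"FUSED"`.
#' @param F,n_i,d_rh,nu,K_E model parameters as in [eye_geometry()] and
#'   [cost_breakdown()].
#' @param equivalents per-pixel rhabdomere-equivalent override.
#' @param tol relative tolerance on the matched cost (default 1e-9).
#' @return radius `R` in micrometres.
#' @export
solve_radius_for_cost <- function(C_tot, D, L, eye_type = "NS",
                                  F = 2, n_i = 1.34, d_rh = 1.9,
                                  nu = 230, K_E = 0, equivalents = NULL,
                                  tol = 1e-9) {
  stopifnot(C_tot > 0, D > 0, L >= 0)
  if (is.null(equivalents)) equivalents <- rhabdomere_equivalents(eye_type)
  f_prime <- focal_distance(D, F, n_i)
  lo <- f_prime + L
  c_lo <- apposition_cost_at_radius(lo, D, L, f_prime, nu, K_E, equivalents)
  if (C_tot < c_lo * (1 - 1e-12)) {
    stop(sprintf(
      "infeasible pair: minimum cost at R = f' + L is %.4g > budget %.4g",
      c_lo, C_tot))
  }
  if (C_tot <= c_lo) return(lo)
  hi <- 2 * lo
  while (apposition_cost_at_radius(hi, D, L, f_prime, nu, K_E,
                                   equivalents) < C_tot) {
    hi <- hi * 2
    if (hi > 1e12) stop("failed to bracket the cost constraint")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    c_mid <- apposition_cost_at_radius(mid, D, L, f_prime, nu, K_E,
                                       equivalents)
    if (abs(c_mid - C_tot) <= tol * C_tot) return(mid)
    if (c_mid < C_tot) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Solve a simple eye's rhabdom length from the cost constraint
#'
#' For a simple eye, `D` fixes the interreceptor angle, so the free
#' variable along the fixed-cost contour is `L`. Total cost is strictly
#' increasing in `L`; bisection from `L = 0` upward.
#'
#' @inheritParams solve_radius_for_cost
#' @param use_f_prime see [simple_eye_volumes()].
#' @return rhabdom length `L` in micrometres.
#' @export
solve_simple_length_for_cost <- function(C_tot, D, F = 2, n_i = 1.34,
                                         d_rh = 1.9, nu = 230, K_E = 0,
                                         equivalents = 3,
                                         use_f_prime = FALSE, tol = 1e-9) {
  stopifnot(C_tot > 0, D > 0)
  f <- if (use_f_prime) F * n_i * D else D * F
  dphi <- simple_eye_sampling(D, F, d_rh)
  dens <- pixel_density(dphi)
  cost_at <- function(L) {
    pi / 3 * (f + L)^3 + K_E * equivalents * nu * L * dens
  }
  c0 <- cost_at(0)
  if (C_tot < c0 * (1 - 1e-12)) {
    stop(sprintf("infeasible: optics alone cost %.4g > budget %.4g",
                 c0, C_tot))
  }
  if (C_tot <= c0) return(0)
  hi <- max(D, 1)
  while (cost_at(hi) < C_tot) {
    hi <- hi * 2
    if (hi > 1e9) stop("failed to bracket the cost constraint")
  }
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    c_mid <- cost_at(mid)
    if (abs(c_mid - C_tot) <= tol * C_tot) return(mid)
    if (c_mid < C_tot) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
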