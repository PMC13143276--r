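#' Load packaged eye-region measurements
#'
#' Published morphological measurements of insect eye regions, transcribed
#' as shipped: `"ns"` holds 12 Dipteran neural-superposition eye regions
#' from 7 species; `"fused"` holds the fused-rhabdom apposition eye
#' regions of mantid, dragonfly and honeybee. The fused table carries 17
#' rows as printed in its source (whose own prose counts 16 regions).
#' Columns: `species`, `region`, `eye_type`, `D_um`, `dphi_deg`, `L_um`,
#' `f_um`, `f_prime_um`, `F`, `source`. A few dragonfly rows omit the
#' F-number; the loader fills them from the nearest row of the same
#' species block that prints one (matching the table's visual layout) and
#' flags them in `F_inherited`.
#'
#' @param table `"ns"` or `"fused"`, or ignored when `path` is given.
#' @param path optional path to an external CSV with the same header.
#' @return data.frame of class `eye_measurements`.
#' @examples
#' nrow(load_measurements("ns")) # 12
#' @export
load_measurements <- function(table = c("ns", "fused"), path = NULL) {
  if (is.null(path)) {
    table <- match.arg(table)
    path <- system.file("extdata", paste0(table, "_eyes.csv"),
                        package = "eyecost", mustWork = TRUE)
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "region", "eye_type", "D_um", "dphi_deg", "L_um",
            "f_um", "f_prime_um", "F", "source")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("measurement table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(d))) {
    for (fld in c("D_um", "dphi_deg", "L_um")) {
      v <- d[[fld]][i]
      if (!is.finite(v) || v <= 0) {
        stop(sprintf("row %d (%s, %s): %s must be positive, got %s",
                     i, d$species[i], d$region[i], fld, format(v)))
      }
    }
    if (!d$eye_type[i] %in% c("NS", "FUSED")) {
      stop(sprintf("row %d: unknown eye_type '%s'", i, d$eye_type[i]))
    }
  }
  d$F_inherited <- FALSE
  if (anyNA(d$F)) {
    for (i in which(is.na(d$F))) {
      block <- which(d$species == d$species[i] & !is.na(d$F))
      if (length(block)) {
        nearest <- block[order(abs(block - i), block)][1]
        d$F[i] <- d$F[nearest]
        d$F_inherited[i] <- TRUE
      }
    }
  }
  class(d) <- c("eye_measurements", "data.frame")
  d
}

#' Cost decomposition of measured eye regions
#'
#' Inserts each row's `L`, `D`, `delta_phi` and `f'` into the spherical
#' shell formulae (`R = D / delta_phi`) to obtain the specific volumes of
#' optics and photoreceptor array. Rows without a tabulated focal distance
#' get `f' = default_F * n_i * D`. Geometrically infeasible rows
#' (`R < f' + L`) are reported by species and region and returned as `NA`.
#'
#' @param meas an [load_measurements()] table (or compatible data.frame).
#' @param n_i internal refractive index used when deriving `f'`.
#' @param default_F F-number used when deriving `f'` (default 2).
#' @return data.frame with the identifying columns plus `R_um`, `V_o`,
#'   `V_ph`, `V_tot` (µm³ sr⁻¹), `p` (eye parameter, µm rad) and
#'   `Vph_pct` (photoreceptor array as % of total volume).
#' @examples
#' costs <- empirical_costs(load_measurements("ns"))
#' signif(costs$V_tot[costs$species == "Drosophila melanogaster"], 2)
#' @export
empirical_costs <- function(meas, n_i = 1.34, default_F = 2) {
  stopifnot(is.data.frame(meas), nrow(meas) >= 1)
  dphi <- deg_to_rad(meas$dphi_deg)
  f_prime <- ifelse(is.finite(meas$f_prime_um), meas$f_prime_um,
                    default_F * n_i * meas$D_um)
  R <- meas$D_um / dphi
  bad <- R < f_prime + meas$L_um
  if (any(bad)) {
    warning("geometrically infeasible rows (R < f' + L): ",
            paste(sprintf("%s / %s", meas$species[bad], meas$region[bad]),
                  collapse = "; "))
  }
  V_o <- ifelse(bad, NA_real_, (R^3 - (R - f_prime)^3) / 3)
  V_ph <- ifelse(bad, NA_real_,
                 ((R - f_prime)^3 - (R - f_prime - meas$L_um)^3) / 3)
  out <- data.frame(
    species = meas$species, region = meas$region, eye_type = meas$eye_type,
    D_um = meas$D_um, dphi_deg = meas$dphi_deg, L_um = meas$L_um,
    f_prime_um = f_prime, R_um = R,
    V_o = V_o, V_ph = V_ph, V_tot = V_o + V_ph,
    p = meas$D_um * dphi,
    Vph_pct = 100 * V_ph / (V_o + V_ph),
    stringsAsFactors = FALSE)
  out
}

#' Summarise the photoreceptor-array volume allocation
#'
#' @param costs an [empirical_costs()] table.
#' @return list with the per-record percentages and their `min_pct`,
#'   `max_pct`, `median_pct` rounded to whole percent (matching the
#'   precision at which such allocations are reported).
#' @export
summarise_allocation <- function(costs) {
  stopifnot(is.data.frame(costs), nrow(costs) >= 1,
            "Vph_pct" %in% names(costs))
  pct <- costs$Vph_pct[is.finite(costs$Vph_pct)]
  list(per_record = costs$Vph_pct,
       min_pct = round(min(pct)),
       max_pct = round(max(pct)),
       median_pct = round(median(pct)))
}
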