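#' Default run configuration
#'
#' The flat key/value set consumed by the command-line interface and the
#' config loader: eye type, optics, scene, transduction and tariff
#' constants, each with the units used throughout the package
#' (micrometres, radians internally / degrees at I/O, seconds, µm³ sr⁻¹).
#'
#' @return named list of defaults.
#' @export
eyecost_defaults <- function() {
  list(
    eye_type = "NS",            # NS | FUSED | SIMPLE
    optics_mode = "COG",        # COG | WOM
    F = 2,                      # F-number
    n_i = 1.34,                 # internal refractive index
    d_rh = 1.9,                 # rhabdom(ere) diameter, um
    nu = 230,                   # microvilli per um of rhabdomere
    K_E = 0,                    # energy tariff, um^3 per microvillus
    lambda = 0.5,               # wavelength, um
    wom_coefficient = 1.26,
    tau_r = 0.1,                # microvillus cycling time, s
    tau = 0.001,                # bump time constant, s
    alpha = 3.12,
    tau_d = 0.0014,             # latency-dispersion time constant, s
    alpha_d = 2,
    contrast = 0.4,
    sigma_v = 1,                # rad/s
    band_lo_deg = 50,           # degrees per cycle, band lower edge
    band_hi_deg = 1.5,
    O_vil_light = 3.24e-9,      # mm^3 O2 per microvillus per hr
    O_vil_dark = 1.08e-9,
    sFMR = 30,                  # mm^3 O2 / mg / hr, flight
    RMR = 2.6,                  # mm^3 O2 / mg / hr, rest
    T_F = 12,                   # hours flying per day
    DL = 12,                    # hours of daylight per day
    simple_eye_uses_f_prime = FALSE,
    fr_nodes = 64, ft_nodes = 48, ft_max = 2000,
    tail_tol = 1e-4, f_cut_factor = 3
  )
}

#' Load and resolve a run configuration
#'
#' Reads a flat YAML or JSON key/value file (chosen by extension) and
#' merges it over [eyecost_defaults()]; unknown keys are rejected so typos
#' fail loudly.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @param overrides named list merged last (e.g. parsed CLI flags).
#' @return resolved configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- eyecost_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yml", "yaml")) {
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      stop("config must be .yaml/.yml or .json, got .", ext)
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    }
    cfg <- modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  if (!cfg$eye_type %in% c("NS", "FUSED", "SIMPLE")) {
    stop("eye_type must be NS, FUSED or SIMPLE")
  }
  if (!cfg$optics_mode %in% c("COG", "WOM")) {
    stop("optics_mode must be COG or WOM")
  }
  numeric_keys <- setdiff(names(cfg),
                          c("eye_type", "optics_mode",
                            "simple_eye_uses_f_prime"))
  for (k in numeric_keys) {
    if (!is.numeric(cfg[[k]]) || !is.finite(cfg[[k]]) || cfg[[k]] < 0) {
      stop("config key '", k, "' must be a non-negative number")
    }
  }
  cfg
}

#' Write the resolved configuration next to an output file
#'
#' Every artifact the CLI writes is accompanied by a JSON echo of the
#' fully resolved configuration, so a run can be reproduced exactly from
#' its outputs.
#'
#' @param cfg configuration list.
#' @param out_path path of the artifact; the sidecar is
#'   `<out_path>.config.json`.
#' @return the sidecar path, invisibly.
#' @export
write_config_sidecar <- function(cfg, out_path) {
  sidecar <- paste0(out_path, ".config.json")
  jsonlite::write_json(cfg, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}
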