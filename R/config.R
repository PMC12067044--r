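#' Model configuration with base-case defaults
#'
#' Every physical constant, correlation coefficient and operating choice of
#' the model lives in this nested configuration; nothing is hard-coded in
#' the solver, so any value (including the Henry compilation constants) can
#' be overridden.  The defaults describe the base case: a 600 m3 bubble
#' column (aspect ratio 6, 95% filled), operated as a chemostat at
#' D = 0.15 1/h, 30 C, 1.2 bar overhead pressure, sparged with pure O2, a
#' dissolved-O2 setpoint of 0.069 mmol/kg, ammonia fed at 200 g/kg with a
#' 1 g/kg residual, and ethanol-limited growth with mu_max = 0.22 1/h,
#' Y_xs_max = 0.63 g/g, m_S = 0.005 mol_S/(mol_x h), K_S = 5e-4 mol/kg.
#'
#' @param overrides named nested list of values to override, e.g.
#'   `list(operation = list(y_O2_in = 0.21))` for air sparging.  Unknown
#'   keys are rejected.
#' @return Object of class `scp_config`: a validated nested list with
#'   blocks `geometry`, `operation`, `kinetics`, `biomass`, `substrate`,
#'   `correlations`, `properties`, `cooling`.
#' @examples
#' cfg <- scp_config()
#' air <- scp_config(list(operation = list(y_O2_in = 0.21)))
#' @export
scp_config <- function(overrides = list()) {
  cfg <- .default_config()
  if (length(overrides)) cfg <- .merge_config(cfg, overrides, path = "")
  .validate_config(cfg)
  structure(cfg, class = "scp_config")
}

.default_config <- function() {
  p <- physical_properties()
  list(
    geometry = list(V_R = 600, aspect_ratio = 6, fill_fraction = 0.95),
    operation = list(
      D = 0.15,                 # dilution rate = growth rate, 1/h
      T = 30,                   # broth temperature, C
      p_top = 1.2,              # absolute overhead pressure, bar
      y_O2_in = 1,              # inlet O2 mole fraction (1 pure O2, 0.21 air)
      C_O2_set = 6.9e-5,        # dissolved O2 setpoint, mol/kg
      C_NH3_residual = 1,       # residual dissolved NH3 target, g/kg
      N_feed_concentration = 200, # NH3 concentration of the N feed, g/kg
      vsG_mean = 0.30,          # target mean superficial gas velocity, m/s
      vsG_top = NULL            # alternative: specify the top velocity
    ),
    kinetics = list(mu_max = 0.22, Y_xs_max = 0.63, m_S = 0.005,
                    K_S = 5e-4, qS_max = NULL),
    biomass = list(formula = "CH1.8O0.5N0.2"),
    substrate = list(formula = "C2H6O"),
    correlations = .default_correlations(),
    properties = list(
      henry_ref = as.list(p$henry_ref),           # mol/(kg bar) at T_ref
      henry_vant_hoff = as.list(p$henry_vant_hoff), # K
      diffusivity = as.list(p$diffusivity),       # m2/s (only the ratio matters)
      rho_L = p$rho_L, cp = p$cp, dH_evap = p$dH_evap,
      heat_per_O2 = p$heat_per_O2, U = p$U,
      antoine = as.list(p$antoine), T_ref = p$T_ref
    ),
    cooling = list(
      dT_lm = 15,               # log-mean temperature difference, K
      dT_loop = 15,             # broth temperature drop over the loop, K
      unit_area_max = 430,      # largest catalogue SAT exchanger, m2
      unit_area_design = 400,   # nominal design area per unit, m2
      tube_id = 0.019,          # tube internal diameter, m
      tube_length = 6.1,        # tube length, m
      tubes_per_unit = 1269,    # tube count of the catalogue unit
      scale_tubes_to_design = TRUE, # scale tube count to the design area
      viscosity = 0.010,        # broth viscosity for shear estimates, Pa s
      coil_pipe_ratio = 30      # internal coil pipe diameter = D_R / ratio
    )
  )
}

.merge_config <- function(base, over, path) {
  if (!is.list(over))
    .scp_stop("invalid_config",
              sprintf("config block '%s' must be a list", path))
  nm <- names(over)
  if (is.null(nm) || any(nm == ""))
    .scp_stop("invalid_config", "config overrides must be fully named")
  for (k in nm) {
    full <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(base))
      .scp_stop("invalid_config", sprintf("unknown config key '%s'", full))
    if (is.list(base[[k]]) && !is.null(base[[k]]) && is.list(over[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], over[[k]], full)
    } else {
      base[k] <- list(over[[k]])  # keeps the key when the value is NULL
    }
  }
  base
}

.validate_config <- function(cfg) {
  chk <- function(ok, key, want) {
    if (!ok) .scp_stop("invalid_config",
                       sprintf("config key '%s' invalid: expected %s", key, want))
  }
  g <- cfg$geometry
  chk(g$V_R > 0, "geometry$V_R", "volume > 0 m3")
  chk(g$fill_fraction > 0 && g$fill_fraction <= 1,
      "geometry$fill_fraction", "a fraction in (0, 1]")
  o <- cfg$operation
  chk(o$D > 0, "operation$D", "dilution rate > 0 1/h")
  chk(o$D < cfg$kinetics$mu_max, "operation$D",
      "dilution rate below mu_max (washout otherwise)")
  chk(o$T > 0 && o$T < 100, "operation$T", "temperature in (0, 100) C")
  chk(o$p_top > 0, "operation$p_top", "pressure > 0 bar")
  chk(o$y_O2_in > 0 && o$y_O2_in <= 1, "operation$y_O2_in",
      "mole fraction in (0, 1]")
  chk(o$C_O2_set >= 0, "operation$C_O2_set", "concentration >= 0 mol/kg")
  chk(o$N_feed_concentration > 0, "operation$N_feed_concentration",
      "concentration > 0 g/kg")
  if (!is.null(o$vsG_mean)) chk(o$vsG_mean > 0, "operation$vsG_mean", "> 0 m/s")
  k <- cfg$kinetics
  chk(k$mu_max > 0 && k$Y_xs_max > 0 && k$K_S > 0 && k$m_S >= 0,
      "kinetics", "positive kinetic parameters")
  chk(cfg$cooling$viscosity > 0, "cooling$viscosity", "viscosity > 0 Pa s")
  invisible(cfg)
}

# Constructors for the model objects embedded in a config ----------------

.cfg_properties <- function(cfg) {
  p <- cfg$properties
  physical_properties(
    henry_ref = unlist(p$henry_ref), henry_vant_hoff = unlist(p$henry_vant_hoff),
    diffusivity = unlist(p$diffusivity), rho_L = p$rho_L, cp = p$cp,
    dH_evap = p$dH_evap, heat_per_O2 = p$heat_per_O2, U = p$U,
    antoine = unlist(p$antoine), T_ref = p$T_ref)
}

.cfg_geometry <- function(cfg) {
  g <- cfg$geometry
  reactor_geometry(g$V_R, g$aspect_ratio, g$fill_fraction)
}

.cfg_kinetics <- function(cfg) {
  k <- cfg$kinetics
  kinetic_parameters(k$mu_max, k$Y_xs_max, k$m_S, k$K_S, k$qS_max)
}

.cfg_stoichiometry <- function(cfg, mu = cfg$operation$D) {
  process_reaction(mu, .cfg_kinetics(cfg),
                   parse_chemical_formula(cfg$biomass$formula),
                   parse_chemical_formula(cfg$substrate$formula))
}

#' Read or write a configuration file
#'
#' Configurations are stored as YAML mirroring the nested structure of
#' [scp_config()]; an empty file yields the full base-case defaults.
#' Loading validates every key (unknown keys and out-of-range values are
#' rejected with the offending key named).
#'
#' @param path file path.
#' @return `load_config()` returns an `scp_config`; `write_config()`
#'   invisibly returns `path`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    .scp_stop("invalid_config", sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  scp_config(raw)
}

#' @rdname load_config
#' @param config an `scp_config` object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Changes iff any configuration value changes; used in run manifests so a
#' report can be traced back to the exact inputs that produced it.
#'
#' @param config an `scp_config` object.
#' @return An md5 string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(config), control = "all"),
                   collapse = "\n"), f)
  unname(tools::md5sum(f))
}
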