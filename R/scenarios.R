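# Named sensitivity scenarios over the core solver, and the dilution-rate
# study that motivates the base-case D.

#' Define a sensitivity scenario
#'
#' A scenario is a named set of configuration overrides applied to a copy
#' of the baseline configuration (the baseline is never mutated).
#'
#' @param name scenario label.
#' @param overrides nested override list as accepted by [scp_config()].
#' @return Object of class `scp_scenario`.
#' @seealso [scenario_presets()] for the built-in scenarios.
#' @export
scenario <- function(name, overrides = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, overrides = overrides),
            class = "scp_scenario")
}

#' Built-in sensitivity scenarios
#'
#' \describe{
#'   \item{yield10}{maximum biomass yield raised 10% (0.63 to 0.693 g/g).}
#'   \item{ks10}{substrate affinity constant lowered tenfold (a more
#'     efficient uptake system evolving in continuous culture).}
#'   \item{hot45}{fermentation at 45 C with unchanged microbial parameters
#'     (faster transfer, lower O2 solubility, cheaper cooling utility).}
#'   \item{coalescence3}{coalescence-inhibited broth: kLa tripled at an
#'     unchanged driving force.}
#'   \item{air}{air instead of pure O2 (inlet O2 fraction 0.21, N2 balance
#'     active).}
#' }
#'
#' @return Named list of [scenario()] objects.
#' @export
scenario_presets <- function() {
  list(
    yield10 = scenario("yield10",
                       list(kinetics = list(Y_xs_max = 0.63 * 1.10))),
    ks10 = scenario("ks10", list(kinetics = list(K_S = 5e-4 / 10))),
    hot45 = scenario("hot45", list(operation = list(T = 45))),
    coalescence3 = scenario("coalescence3",
                            list(correlations = list(coalescence_factor = 3))),
    air = scenario("air", list(operation = list(y_O2_in = 0.21)))
  )
}

#' Run a scenario against a baseline over a velocity grid
#'
#' Solves both configurations at every grid point and tabulates the key
#' metrics side by side with their percentage changes.
#'
#' @param scen an [scenario()] object or the name of a built-in preset.
#' @param config baseline [scp_config()].
#' @param vsG_mean_grid mean superficial gas velocities to compare at, m/s.
#' @return Object of class `scp_comparison`: data frame with, per grid
#'   point and per metric (`N_O2`, `O2_utilization`, `C_x`, `R_x_kg`,
#'   `Q_cool`), the baseline value, scenario value and percentage change.
#'   Failed points carry `NA`.
#' @export
run_scenario <- function(scen, config = scp_config(),
                         vsG_mean_grid = c(0.04, 0.10, 0.20, 0.30)) {
  if (is.character(scen)) {
    presets <- scenario_presets()
    if (!scen %in% names(presets))
      .scp_stop("invalid_config", sprintf(
        "unknown scenario '%s' (built-ins: %s)", scen,
        paste(names(presets), collapse = ", ")))
    scen <- presets[[scen]]
  }
  # apply overrides on top of the supplied baseline, not the defaults
  cfg2 <- .merge_config(unclass(config), scen$overrides, path = "")
  cfg2 <- structure(.validate_config(cfg2), class = "scp_config")

  metrics <- function(cfg, v) {
    res <- tryCatch(solve_operating_point(cfg, vsG_mean = v),
                    scp_error = function(e) NULL)
    if (is.null(res))
      return(c(N_O2 = NA, O2_utilization = NA, C_x = NA, R_x_kg = NA,
               Q_cool = NA))
    c(N_O2 = res$N_O2, O2_utilization = res$O2_utilization,
      C_x = res$C_x, R_x_kg = res$R_x_kg,
      Q_cool = heat_balance(res)$Q_cool)
  }
  rows <- lapply(vsG_mean_grid, function(v) {
    b <- metrics(config, v)
    s <- metrics(cfg2, v)
    data.frame(vsG_mean = v, metric = names(b), baseline = unname(b),
               scenario = unname(s),
               delta_pct = unname(100 * (s - b) / b), row.names = NULL)
  })
  structure(do.call(rbind, rows),
            scenario = scen$name, class = c("scp_comparison", "data.frame"))
}

#' Yield and residual substrate as a function of the dilution rate
#'
#' Stoichiometry-only study (no gas-phase solve): over a grid of dilution
#' rates, the realized biomass yield rises toward the maximum as the
#' maintenance share of substrate shrinks, while the residual substrate
#' concentration rises hyperbolically and diverges toward washout.
#'
#' @param D_grid dilution rates, 1/h.
#' @param config an [scp_config()].
#' @return Data frame with `D`, `Y_xs` (g/g), `C_S` (mol/kg), `qS`
#'   (mol_S/(mol_x h), negative) and `washout` (logical; washout rows carry
#'   `NA` values).
#' @export
dilution_rate_study <- function(D_grid = seq(0.01, 0.21, by = 0.01),
                                config = scp_config()) {
  params <- .cfg_kinetics(config)
  biomass <- parse_chemical_formula(config$biomass$formula)
  substrate <- parse_chemical_formula(config$substrate$formula)
  rows <- lapply(D_grid, function(D) {
    res <- tryCatch(
      {
        st <- process_reaction(D, params, biomass, substrate)
        data.frame(D = D, Y_xs = st$Y_xs, C_S = st$residual_CS,
                   qS = st$qS, washout = FALSE)
      },
      scp_washout = function(e)
        data.frame(D = D, Y_xs = NA_real_, C_S = NA_real_, qS = NA_real_,
                   washout = TRUE))
    res
  })
  do.call(rbind, rows)
}
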