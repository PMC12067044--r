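# Staged steady-state solver: gas-phase root-find on the bottom superficial
# velocity, then explicit liquid-side balances.

# Everything the gas phase implies for a (vsG_bot, vsG_top) pair.  The gas
# hold-up, bottom pressure and velocities are mutually consistent within a
# single evaluation (no stale values): eps_G follows from the log-mean
# velocity and p_bot from eps_G.
.gas_state <- function(vsG_bot, vsG_top, stoich, cfg, props, geom) {
  op <- cfg$operation
  T_K <- op$T + 273.15
  vsG_mean <- log_mean(vsG_top, vsG_bot)
  eps_G <- gas_holdup(vsG_mean, cfg$correlations)
  M_L <- props$rho_L * (1 - eps_G) * geom$V_aerated
  p_bot <- bottom_pressure(op$p_top, eps_G, geom, props$rho_L)
  FG_out <- molar_gas_flow(vsG_top, op$p_top, T_K, geom)
  FG_in <- molar_gas_flow(vsG_bot, p_bot, T_K, geom)
  y_W <- water_vapor_pressure(T_K, props) / op$p_top
  RQ <- stoich$RQ

  # N_O2 implied by the gas balances: total balance with N_CO2 = -RQ N_O2
  # and the equilibrium evaporation flux
  N_O2_bal <- (FG_in - FG_out * (1 - y_W)) / ((1 - RQ) * M_L)
  y_O2_out <- (FG_in * op$y_O2_in - N_O2_bal * M_L) / FG_out
  y_CO2_out <- RQ * N_O2_bal * M_L / FG_out
  y_N2_out <- FG_in * (1 - op$y_O2_in) / FG_out

  p_eff <- switch(cfg$correlations$pressure_mean,
                  log = log_mean(p_bot, op$p_top),
                  arithmetic = (p_bot + op$p_top) / 2,
                  top = op$p_top,
                  .scp_stop("invalid_config",
                            "correlations$pressure_mean must be 'log', 'arithmetic' or 'top'"))
  kla_O2 <- kla(vsG_mean, op$T, "O2", props, cfg$correlations)

  # N_O2 implied by transfer at the off-gas composition
  N_O2_tr <- kla_O2 *
    (henry_coefficient("O2", T_K, props) * y_O2_out * p_eff - op$C_O2_set)

  list(vsG_bot = vsG_bot, vsG_top = vsG_top, vsG_mean = vsG_mean,
       eps_G = eps_G, M_L = M_L, p_top = op$p_top, p_bot = p_bot,
       p_eff = p_eff, FG_in = FG_in, FG_out = FG_out,
       y_O2_out = y_O2_out, y_CO2_out = y_CO2_out, y_N2_out = y_N2_out,
       y_W_out = y_W, kla_O2 = kla_O2,
       N_O2_balance = N_O2_bal, N_O2_transfer = N_O2_tr,
       residual = N_O2_bal - N_O2_tr)
}

#' Gas-phase objective function of the staged solver
#'
#' Evaluates the O2 transfer rate twice for a candidate pair of bottom and
#' top superficial velocities: (a) from the gas-phase material balances
#' (total balance with `N_CO2 = -RQ * N_O2` and the evaporation flux) and
#' (b) from the kLa transfer law at the implied off-gas composition.  The
#' staged solver drives the difference (a) - (b) to zero by varying
#' `vsG_bot`.
#'
#' @param vsG_bot,vsG_top superficial gas velocities at the bottom and top
#'   of the column, m/s.
#' @param stoich an [process_reaction()] stoichiometry at the operating
#'   growth rate.
#' @param config an [scp_config()].
#' @return The residual (a) - (b), mol/(kg_L h), with the full gas state in
#'   attribute `"state"`.
#' @export
gas_phase_residual <- function(vsG_bot, vsG_top,
                               stoich = NULL, config = scp_config()) {
  if (vsG_bot <= 0 || vsG_top <= 0)
    .scp_stop("domain_error", "velocities must be positive")
  if (is.null(stoich)) stoich <- .cfg_stoichiometry(config)
  st <- .gas_state(vsG_bot, vsG_top, stoich, config,
                   .cfg_properties(config), .cfg_geometry(config))
  ys <- c(st$y_O2_out, st$y_CO2_out, st$y_N2_out, st$y_W_out)
  if (any(ys < -1e-9) || any(ys > 1 + 1e-9))
    .scp_stop("infeasible", sprintf(
      "infeasible off-gas composition (y_O2 = %.3g, y_CO2 = %.3g)",
      st$y_O2_out, st$y_CO2_out))
  structure(st$residual, state = st)
}

# root-find on vsG_bot for a fixed vsG_top; returns the converged gas state
.solve_gas_phase <- function(vsG_top, stoich, cfg, props, geom,
                             rel_tol = 1e-9) {
  f <- function(vb) .gas_state(vb, vsG_top, stoich, cfg, props, geom)$residual
  # bracket a sign change on a geometric grid below/around vsG_top
  grid <- vsG_top * exp(seq(log(1e-3), log(5), length.out = 60))
  fv <- vapply(grid, f, numeric(1))
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0)
    .scp_stop("no_steady_state", sprintf(
      "O2 transfer cannot match the gas balances at vsG_top = %.3g m/s", vsG_top))
  i <- idx[1]
  r <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = vsG_top * 1e-13,
                      maxiter = 1000)
  st <- .gas_state(r$root, vsG_top, stoich, cfg, props, geom)
  scale <- max(abs(st$N_O2_balance), abs(st$N_O2_transfer))
  if (abs(st$residual) > rel_tol * scale)
    .scp_stop("no_steady_state", sprintf(
      "gas-phase root-find did not converge (relative residual %.2g)",
      abs(st$residual) / scale))
  st
}

#' Solve one steady-state operating point
#'
#' The staged solution procedure: the process-reaction stoichiometry at
#' `mu = D` fixes the respiratory quotient; a bracketed scalar root-find on
#' the bottom superficial velocity then makes the balance-derived and
#' transfer-derived O2 fluxes agree; finally all liquid-side quantities
#' follow explicitly (liquid mass via the gas hold-up, production rates via
#' the stoichiometry, feed flows from the liquid balances honoring the
#' residual substrate and ammonia targets).
#'
#' The gas velocity may be specified either as the column log-mean
#' (`vsG_mean`, the reporting axis) or as the top velocity (`vsG_top`, the
#' paper-style iteration variable); with a mean target an outer root-find
#' maps it to the corresponding top velocity.
#'
#' @param config an [scp_config()]; `config$operation` carries the
#'   operating point (D, T, pressures, oxygen fraction, velocity target).
#' @param vsG_mean,vsG_top optional overrides of the velocity specification
#'   (m/s); at most one may be given.
#' @param quiet suppress the out-of-range correlation warning during
#'   root-find iterations (the converged point is still checked).
#' @return Object of class `scp_solution`; see Details.
#' @details The returned object contains the converged gas state (flows
#'   mol/h, mole fractions, pressures bar, velocities m/s, hold-up, kLa
#'   1/h), the liquid mass `M_L` (kg), transfer rates `N_O2`, `N_CO2`,
#'   `N_W` (mol/(kg_L h)), production rates `R_*` (mol/h), the biomass
#'   concentration `C_x` (g/kg) and production `R_x_kg` (kg/h), dissolved
#'   concentrations `C_S`, `C_CO2` (mol/kg), feed flows `F_S_feed`,
#'   `F_N_feed`, outflow `F_L_out` (kg/h), the feed substrate concentration
#'   `C_S_in` (g/kg), the O2 and substrate utilizations (%), and the
#'   stoichiometry and configuration used.
#' @examples
#' \donttest{
#' sol <- solve_operating_point(scp_config(), vsG_mean = 0.30)
#' sol$N_O2          # ~1.1 mol/(kg h)
#' sol$C_x           # ~114 g/kg
#' }
#' @export
solve_operating_point <- function(config = scp_config(), vsG_mean = NULL,
                                  vsG_top = NULL, quiet = TRUE) {
  cfg <- config
  if (!is.null(vsG_mean) && !is.null(vsG_top))
    .scp_stop("invalid_config", "give either vsG_mean or vsG_top, not both")
  if (!is.null(vsG_mean)) cfg$operation$vsG_mean <- vsG_mean
  if (!is.null(vsG_top)) {
    cfg$operation$vsG_top <- vsG_top
    cfg$operation$vsG_mean <- NULL
  }
  props <- .cfg_properties(cfg)
  geom <- .cfg_geometry(cfg)
  stoich <- .cfg_stoichiometry(cfg)

  solve_inner <- function(vt) .solve_gas_phase(vt, stoich, cfg, props, geom)
  run <- function(expr) if (quiet) suppressWarnings(expr) else expr

  if (!is.null(cfg$operation$vsG_top)) {
    st <- run(solve_inner(cfg$operation$vsG_top))
  } else {
    target <- cfg$operation$vsG_mean
    if (is.null(target))
      .scp_stop("invalid_config", "no velocity specification in config")
    # the log-mean lies below vsG_top whenever the gas shrinks, so bracket
    # the outer root between the target itself and a few times the target
    outer_f <- function(vt) solve_inner(vt)$vsG_mean - target
    hi <- target * 2
    f_hi <- run(outer_f(hi))
    while (f_hi < 0 && hi < target * 16) {
      hi <- hi * 2
      f_hi <- run(outer_f(hi))
    }
    if (f_hi < 0)
      .scp_stop("no_steady_state",
                "could not bracket the requested mean gas velocity")
    vt <- run(stats::uniroot(outer_f, c(target * (1 + 1e-9), hi),
                             tol = target * 1e-12, maxiter = 1000)$root)
    st <- run(solve_inner(vt))
  }
  # re-check the correlation validity window once, audibly
  if (st$vsG_mean < 0.04 - 1e-9 || st$vsG_mean > 0.30 + 1e-9)
    .scp_warn("correlation_range", sprintf(
      "converged vsG_mean = %.3g m/s outside the 0.04-0.30 m/s correlation window",
      st$vsG_mean))
  .finish_solution(st, stoich, cfg, props, geom)
}

# explicit liquid-side balances given a converged gas state
.finish_solution <- function(st, stoich, cfg, props, geom) {
  op <- cfg$operation
  T_K <- op$T + 273.15
  nu <- stoich$coefficients
  M_x <- stoich$biomass$molar_mass
  M_S <- stoich$substrate$molar_mass

  if (st$y_O2_out < -1e-9 || st$y_CO2_out < -1e-9)
    .scp_stop("infeasible", "converged gas composition is infeasible")

  N_O2 <- st$N_O2_balance
  N_CO2 <- -stoich$RQ * N_O2
  N_W <- -st$y_W_out * st$FG_out / st$M_L

  # production rates from the stoichiometry, mol/h
  R_O2 <- -N_O2 * st$M_L                      # consumption (Eq. 5)
  R_x <- N_O2 * st$M_L / abs(nu[["O2"]])
  R_S <- -abs(nu[["substrate"]]) * R_x
  R_CO2 <- nu[["CO2"]] * R_x
  R_NH3 <- -abs(nu[["NH3"]]) * R_x

  F_L_out <- op$D * st$M_L                    # kg/h
  C_x_molar <- R_x / F_L_out                  # mol/kg
  C_x <- C_x_molar * M_x                      # g/kg
  C_S <- stoich$residual_CS                   # mol/kg

  # dissolved CO2 from the transfer law with N_CO2 = -RQ N_O2
  kla_CO2 <- kla(st$vsG_mean, op$T, "CO2", props, cfg$correlations)
  C_CO2 <- henry_coefficient("CO2", T_K, props) * st$y_CO2_out * st$p_eff -
    N_CO2 / kla_CO2

  # ammonia feed sized for the residual target (liquid NH3 balance, Eq. 9)
  C_NH3 <- op$C_NH3_residual / .M_NH3         # mol/kg residual
  C_NH3_in <- op$N_feed_concentration / .M_NH3
  F_N_feed <- (F_L_out * C_NH3 - R_NH3) / C_NH3_in

  # total liquid mass balance (Eq. 10) closes the substrate feed
  net_gas_mass <- (N_O2 * .M_O2 + N_CO2 * .M_CO2 + N_W * .M_H2O) *
    st$M_L / 1000                             # kg/h, gas to liquid
  F_S_feed <- F_L_out - F_N_feed - net_gas_mass
  if (F_S_feed <= 0)
    .scp_stop("infeasible", "substrate feed flow is non-positive")

  # substrate balance (Eq. 7) gives the required feed concentration
  C_S_in_molar <- (F_L_out * C_S - R_S) / F_S_feed
  C_S_in <- C_S_in_molar * M_S                # g/kg

  O2_util <- 100 * (1 - st$FG_out * st$y_O2_out / (st$FG_in * op$y_O2_in))
  S_util <- 100 * (1 - F_L_out * C_S / (F_S_feed * C_S_in_molar))

  sol <- c(st, list(
    N_O2 = N_O2, N_CO2 = N_CO2, N_W = N_W, kla_CO2 = kla_CO2,
    R_O2 = R_O2, R_x = R_x, R_S = R_S, R_CO2 = R_CO2, R_NH3 = R_NH3,
    R_x_kg = R_x * M_x / 1000,
    M_L = st$M_L, F_L_out = F_L_out,
    C_x = C_x, C_x_molar = C_x_molar, C_S = C_S, C_CO2 = C_CO2,
    C_O2 = op$C_O2_set, C_NH3 = C_NH3,
    F_N_feed = F_N_feed, F_S_feed = F_S_feed,
    C_S_in = C_S_in, C_S_in_molar = C_S_in_molar,
    C_NH3_in_molar = C_NH3_in,
    net_gas_mass = net_gas_mass,
    O2_utilization = O2_util, ethanol_utilization = S_util,
    stoichiometry = stoich, config = cfg))
  class(sol) <- "scp_solution"
  sol$carbon_balance_error <- carbon_balance_error(sol)
  sol
}

#' Carbon imbalance induced by the staged solution procedure
#'
#' The staged solver equates the CO2 production and transfer rates, which
#' neglects the dissolved CO2 leaving with the liquid outflow; the
#' corresponding carbon appears from nowhere.  Reported here as the
#' percentage of the carbon fed in the substrate stream that additionally
#' leaves as dissolved CO2: `100 * F_L_out C_CO2 / (n_C F_S_feed C_S_in)`.
#' The error shrinks as the gas velocity (and with it the CO2 stripping)
#' increases.
#'
#' @param sol an [solve_operating_point()] solution.
#' @return Percentage error (>= 0).
#' @export
carbon_balance_error <- function(sol) {
  n_C <- sol$stoichiometry$substrate$C
  100 * (sol$F_L_out * sol$C_CO2) /
    (n_C * sol$F_S_feed * sol$C_S_in_molar)
}

#' Sweep the solver over a grid of mean gas velocities
#'
#' One converged operating point per grid value; failures at individual
#' points are recorded and the sweep continues.
#'
#' @param config an [scp_config()].
#' @param vsG_mean_grid monotone grid of mean superficial gas velocities,
#'   m/s (default 14 points over the 0.04-0.30 m/s regime window).
#' @return Object of class `scp_sweep`: list with `table` (one row per
#'   converged point: velocities, gas flows, hold-up, kLa, transfer rate,
#'   off-gas O2 fraction, dissolved CO2, liquid mass, biomass concentration
#'   and production, feed concentration, utilizations, carbon-balance
#'   error), `solutions` (the full solution objects) and `failures`.
#' @export
sweep_operating_points <- function(config = scp_config(),
                                   vsG_mean_grid = seq(0.04, 0.30,
                                                       by = 0.02)) {
  sols <- vector("list", length(vsG_mean_grid))
  fails <- list()
  rows <- vector("list", length(vsG_mean_grid))
  for (i in seq_along(vsG_mean_grid)) {
    v <- vsG_mean_grid[i]
    res <- tryCatch(solve_operating_point(config, vsG_mean = v),
                    scp_error = function(e) e)
    if (inherits(res, "scp_error")) {
      fails[[as.character(v)]] <- conditionMessage(res)
      next
    }
    sols[[i]] <- res
    rows[[i]] <- as.data.frame(res)
  }
  ok <- !vapply(rows, is.null, logical(1))
  structure(list(table = do.call(rbind, rows[ok]),
                 solutions = sols[ok],
                 failures = fails,
                 config = config),
            class = "scp_sweep")
}

#' @export
as.data.frame.scp_solution <- function(x, ...) {
  data.frame(vsG_mean = x$vsG_mean, vsG_top = x$vsG_top,
             vsG_bot = x$vsG_bot,
             FG_in = x$FG_in, FG_out = x$FG_out,
             eps_G = x$eps_G, M_L = x$M_L,
             kla_O2 = x$kla_O2, N_O2 = x$N_O2,
             y_O2_out = x$y_O2_out, y_CO2_out = x$y_CO2_out,
             C_CO2 = x$C_CO2, C_x = x$C_x, R_x_kg = x$R_x_kg,
             F_L_out = x$F_L_out, F_S_feed = x$F_S_feed,
             F_N_feed = x$F_N_feed, C_S_in = x$C_S_in,
             O2_utilization = x$O2_utilization,
             ethanol_utilization = x$ethanol_utilization,
             carbon_balance_error = x$carbon_balance_error)
}

#' @export
print.scp_solution <- function(x, ...) {
  cat(sprintf(paste0(
    "Steady-state operating point (D = %.3g 1/h, y_O2_in = %.2f)\n",
    "  vsG mean/top/bot : %.3f / %.3f / %.3f m/s   eps_G = %.3f\n",
    "  N_O2 = %.3f mol/(kg h)   kLa_O2 = %.0f 1/h   y_O2_out = %.3f\n",
    "  M_L = %.3e kg   C_x = %.1f g/kg   R_x = %.0f kg/h\n",
    "  F_L_out = %.0f kg/h   C_S_in = %.0f g/kg   O2 util = %.1f %%\n"),
    x$config$operation$D, x$config$operation$y_O2_in,
    x$vsG_mean, x$vsG_top, x$vsG_bot, x$eps_G,
    x$N_O2, x$kla_O2, x$y_O2_out,
    x$M_L, x$C_x, x$R_x_kg,
    x$F_L_out, x$C_S_in, x$O2_utilization))
  invisible(x)
}
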