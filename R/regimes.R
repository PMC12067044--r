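# Characteristic-time regime analysis: compares mixing against conversion,
# transfer and flow-through time constants to flag likely spatial gradients
# during scale-up.

#' Internal liquid circulation flow driven by the gas
#'
#' Gas-driven circulation in a bubble column:
#' `F_mix = 0.3 D_R^(5/3) (F_G^V)^(1/3) g^(1/3)` with the volumetric gas
#' flow at column-average conditions.
#'
#' @param geometry an [reactor_geometry()] object.
#' @param FG_V_mean volumetric gas flow at mean column conditions, m3/s.
#' @return Circulation flow, m3/s.
#' @export
mixing_flow <- function(geometry = reactor_geometry(), FG_V_mean) {
  stopifnot(FG_V_mean >= 0)
  0.3 * geometry$D_R^(5 / 3) * FG_V_mean^(1 / 3) * .G_ACC^(1 / 3)
}

#' Characteristic times of a converged operating point
#'
#' Reservoir-over-rate time constants, all in seconds:
#' \describe{
#'   \item{tau_mix_L}{ungassed liquid volume over the gas-driven
#'     circulation flow ([mixing_flow()]).}
#'   \item{tau_mix_G}{gas hold-up volume over the same circulation flow
#'     (the gas circulates with the liquid-driven loop).}
#'   \item{tau_FG}{gas hold-up volume over the volumetric gas throughput at
#'     mean column conditions (gas flow-through).}
#'   \item{tau_S, tau_O2, tau_CO2}{dissolved reservoir over the volumetric
#'     consumption (production for CO2) rate.}
#'   \item{tau_heat}{temperature reservoir `cp dT_allowed` over the
#'     specific heat load.}
#' }
#'
#' @param sol an [solve_operating_point()] solution.
#' @param dT_allowed temperature excursion regarded as tolerable, K.
#' @return Object of class `scp_times` (named list of seconds, plus the
#'   underlying flows).
#' @export
characteristic_times <- function(sol, dT_allowed = 1) {
  cfg <- sol$config
  props <- .cfg_properties(cfg)
  geom <- .cfg_geometry(cfg)
  FG_V_mean <- sol$vsG_mean * geom$A_cross           # m3/s
  F_mix <- mixing_flow(geom, FG_V_mean)
  V_L <- sol$M_L / props$rho_L
  V_G <- sol$eps_G * geom$V_aerated

  r_S <- abs(sol$stoichiometry$qS) * sol$C_x_molar   # mol/(kg h)
  r_CO2 <- sol$stoichiometry$RQ * sol$N_O2
  if (r_S <= 0 || sol$N_O2 <= 0 || r_CO2 <= 0)
    .scp_stop("degenerate", "zero conversion rates: characteristic times undefined")
  hb <- heat_balance(sol)

  structure(list(
    tau_mix_L = V_L / F_mix,
    tau_mix_G = V_G / F_mix,
    tau_FG = V_G / FG_V_mean,
    tau_S = sol$C_S / r_S * 3600,
    tau_O2 = sol$C_O2 / sol$N_O2 * 3600,
    tau_CO2 = sol$C_CO2 / r_CO2 * 3600,
    tau_heat = props$cp * 1000 * dT_allowed / hb$specific_load,
    F_mix = F_mix, FG_V_mean = FG_V_mean,
    dT_allowed = dT_allowed),
    class = "scp_times")
}

#' @export
print.scp_times <- function(x, ...) {
  v <- unlist(x[c("tau_mix_L", "tau_mix_G", "tau_FG", "tau_S", "tau_O2",
                  "tau_CO2", "tau_heat")])
  cat("Characteristic times (s):\n")
  print(round(v, 2))
  invisible(x)
}

#' Flag mechanism pairs likely to develop spatial gradients
#'
#' A gradient in a quantity is only expected when its consumption or
#' production outruns mixing by more than the given ratio (default one
#' order of magnitude): for each conversion mechanism the liquid mixing
#' time is compared against the mechanism time, and the gas flow-through
#' time against gas mixing.
#'
#' @param times an [characteristic_times()] object.
#' @param threshold ratio above which a pair is flagged.
#' @return Data frame with one row per comparison: `mechanism`, `tau`,
#'   `tau_mixing`, `ratio` (mixing over mechanism) and `flagged`.
#' @export
gradient_flags <- function(times, threshold = 10) {
  stopifnot(threshold > 0)
  mech <- c(substrate = times$tau_S, oxygen = times$tau_O2,
            carbon_dioxide = times$tau_CO2, heat = times$tau_heat)
  out <- data.frame(
    mechanism = c(names(mech), "gas_flow_through"),
    tau = c(unname(mech), times$tau_FG),
    tau_mixing = c(rep(times$tau_mix_L, length(mech)), times$tau_mix_G),
    row.names = NULL)
  out$ratio <- out$tau_mixing / out$tau
  # gas flow-through: a gradient is expected when flow outruns mixing,
  # i.e. the convention is the same (slow mixing relative to the mechanism)
  out$flagged <- is.finite(out$ratio) & out$ratio > threshold
  out
}

#' O2 transfer-capacity ratio between column bottom and top
#'
#' Evaluates the local transfer driving force at the bottom (full
#' hydrostatic pressure) and the top of the column.  Under the well-mixed
#' bound the off-gas composition applies at both ends, so only the pressure
#' differs; under the plug-flow bound the bottom sees the inlet gas
#' composition.  The true gas phase lies between the two bounds.
#'
#' @param sol an [solve_operating_point()] solution.
#' @param y_O2_out optional off-gas O2 fraction override (to explore
#'   improved-utilization operation).
#' @return List with `well_mixed` and `plug_flow` bottom/top ratios.
#' @export
transfer_capacity_ratio <- function(sol, y_O2_out = NULL) {
  cfg <- sol$config
  props <- .cfg_properties(cfg)
  T_K <- cfg$operation$T + 273.15
  KH <- henry_coefficient("O2", T_K, props)
  y_out <- if (is.null(y_O2_out)) sol$y_O2_out else y_O2_out
  C <- sol$C_O2
  df <- function(y, p) KH * y * p - C
  list(well_mixed = df(y_out, sol$p_bot) / df(y_out, sol$p_top),
       plug_flow = df(cfg$operation$y_O2_in, sol$p_bot) / df(y_out, sol$p_top))
}
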