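# Shared fixtures and independent oracles for the test suite.

# Steam-table saturation pressures of water (bar), standard reference values.
steam_table <- data.frame(
  T_K = c(278.15, 283.15, 293.15, 298.15, 303.15, 313.15, 323.15),
  p_bar = c(0.008726, 0.012282, 0.023393, 0.031699, 0.042470, 0.073849,
            0.123520)
)

# Frozen compilation values: dissolved gas at 1 bar partial pressure and
# 25 C, g/kg (Sander-type constants times molar mass).
dissolved_1bar_25C <- c(H2 = 0.16e-2, CH4 = 2.52e-2, CO = 2.72e-2)

# Frozen van't Hoff evaluation of the O2 Henry coefficient at 30 C,
# 1.2e-3 * exp(1500 * (1/303.15 - 1/298.15)) mol/(kg bar), computed once
# from the documented compilation constants.
henry_O2_303 <- 1.104449e-3

base_config <- function(...) scp_config(list(...))

solve_base <- function(vsG_mean = 0.30, cfg = scp_config()) {
  solve_operating_point(cfg, vsG_mean = vsG_mean)
}

# Independent simultaneous solve of the full steady-state system: all gas
# and liquid balances at once, written out as raw arithmetic on four
# unknowns (vsG_bot, vsG_top, y_O2_out, y_CO2_out) and solved with a
# generic Newton method (pracma::fsolve).  Shares only the configuration
# constants and the reaction stoichiometry with the staged solver.
simultaneous_solve <- function(vsG_mean_target, cfg = scp_config(),
                               stoich = process_reaction(cfg$operation$D)) {
  op <- cfg$operation
  pr <- cfg$properties
  T_K <- op$T + 273.15
  D_R <- (4 * cfg$geometry$V_R / (cfg$geometry$aspect_ratio * pi))^(1 / 3)
  A <- pi / 4 * D_R^2
  H_aer <- cfg$geometry$fill_fraction * cfg$geometry$aspect_ratio * D_R
  V_aer <- cfg$geometry$fill_fraction * cfg$geometry$V_R
  RQ <- stoich$RQ
  KH_O2 <- pr$henry_ref$O2 * exp(pr$henry_vant_hoff$O2 * (1 / T_K - 1 / pr$T_ref))
  an <- pr$antoine
  psat <- 10^(an$A - an$B / (an$C + op$T)) * 1.01325 / 760
  y_W <- psat / op$p_top

  eqs <- function(x) {
    vb <- x[1]; vt <- x[2]; yO2 <- x[3]; yCO2 <- x[4]
    vm <- (vt - vb) / log(vt / vb)
    eps <- cfg$correlations$holdup_a * vm^cfg$correlations$holdup_b
    ML <- pr$rho_L * (1 - eps) * V_aer
    pbot <- op$p_top + pr$rho_L * (1 - eps) * 9.80665 * H_aer / 1e5
    FGout <- vt * op$p_top * 1e5 * A / (8.314462618 * T_K) * 3600
    FGin <- vb * pbot * 1e5 * A / (8.314462618 * T_K) * 3600
    peff <- (pbot - op$p_top) / log(pbot / op$p_top)
    kla_O2 <- cfg$correlations$kla_a * vm^cfg$correlations$kla_b *
      cfg$correlations$kla_theta^(op$T - 20) *
      cfg$correlations$coalescence_factor * 3600
    N_O2 <- kla_O2 * (KH_O2 * yO2 * peff - op$C_O2_set)
    c(FGin * op$y_O2_in - FGout * yO2 - N_O2 * ML,          # O2 gas
      -FGout * yCO2 + RQ * N_O2 * ML,                       # CO2 gas
      FGin - FGout - (N_O2 - RQ * N_O2 - y_W * FGout / ML) * ML, # total gas
      vm - vsG_mean_target)                                 # velocity spec
  }
  x0 <- c(0.6 * vsG_mean_target, 1.5 * vsG_mean_target, 0.8, 0.15)
  root <- pracma::fsolve(eqs, x0, tol = 1e-12)$x
  vb <- root[1]; vt <- root[2]; yO2 <- root[3]
  vm <- (vt - vb) / log(vt / vb)
  eps <- cfg$correlations$holdup_a * vm^cfg$correlations$holdup_b
  ML <- pr$rho_L * (1 - eps) * V_aer
  pbot <- op$p_top + pr$rho_L * (1 - eps) * 9.80665 * H_aer / 1e5
  peff <- (pbot - op$p_top) / log(pbot / op$p_top)
  kla_O2 <- cfg$correlations$kla_a * vm^cfg$correlations$kla_b *
    cfg$correlations$kla_theta^(op$T - 20) *
    cfg$correlations$coalescence_factor * 3600
  N_O2 <- kla_O2 * (KH_O2 * yO2 * peff - op$C_O2_set)
  M_x <- stoich$biomass$molar_mass
  C_x <- (N_O2 / abs(stoich$coefficients[["O2"]])) * M_x / op$D
  list(N_O2 = N_O2, C_x = C_x, vsG_bot = vb, vsG_top = vt,
       y_O2_out = yO2, M_L = ML)
}

# Residuals of the ten steady-state material balances, evaluated on the
# fields stored in a converged solution, each normalized by its dominant
# term.
table2_residuals <- function(sol) {
  op <- sol$config$operation
  y_N2_in <- 1 - op$y_O2_in
  M_NH3 <- 3 * 1.008 + 14.007
  M_O2 <- 2 * 15.999; M_CO2 <- 12.011 + 2 * 15.999; M_H2O <- 2 * 1.008 + 15.999
  net_mass <- (sol$N_O2 * M_O2 + sol$N_CO2 * M_CO2 + sol$N_W * M_H2O) *
    sol$M_L / 1000
  r <- c(
    O2_gas = (sol$FG_in * op$y_O2_in - sol$FG_out * sol$y_O2_out -
                sol$N_O2 * sol$M_L) / (sol$FG_in * op$y_O2_in),
    CO2_gas = (-sol$FG_out * sol$y_CO2_out - sol$N_CO2 * sol$M_L) /
      (sol$FG_out * max(sol$y_CO2_out, 1e-12)),
    N2_gas = if (y_N2_in > 0)
      (sol$FG_in * y_N2_in - sol$FG_out * sol$y_N2_out) /
        (sol$FG_in * y_N2_in) else 0,
    total_gas = (sol$FG_in - sol$FG_out -
                   (sol$N_O2 + sol$N_CO2 + sol$N_W) * sol$M_L) / sol$FG_in,
    O2_liquid = (sol$N_O2 * sol$M_L + sol$R_O2) / (sol$N_O2 * sol$M_L),
    CO2_liquid = (sol$N_CO2 * sol$M_L + sol$R_CO2) / abs(sol$R_CO2),
    substrate = (sol$F_S_feed * sol$C_S_in_molar - sol$F_L_out * sol$C_S +
                   sol$R_S) / abs(sol$R_S),
    biomass = (sol$R_x - sol$F_L_out * sol$C_x_molar) / sol$R_x,
    NH3 = (sol$F_N_feed * sol$C_NH3_in_molar - sol$F_L_out * sol$C_NH3 +
             sol$R_NH3) / abs(sol$R_NH3),
    total_liquid = (sol$F_S_feed + sol$F_N_feed - sol$F_L_out + net_mass) /
      sol$F_L_out
  )
  abs(r)
}
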