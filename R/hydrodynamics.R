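#' Bubble-column reactor geometry
#'
#' The diameter follows from the vessel volume and the height-over-diameter
#' aspect ratio: `D_R = (4 V_R / (aspect_ratio * pi))^(1/3)`.  The aerated
#' broth occupies `fill_fraction` of the vessel (headspace kept against
#' foaming), so the aerated height is `fill_fraction * H_R`.
#'
#' @param V_R vessel volume, m3.
#' @param aspect_ratio height over diameter, dimensionless.
#' @param fill_fraction fraction of the vessel occupied by aerated broth.
#' @return Object of class `scp_geometry` with `D_R`, `H_R` (m), `A_cross`
#'   (m2), `H_aerated` (m), `V_aerated` (m3).
#' @examples
#' reactor_geometry()$D_R  # 5.03 m
#' @export
reactor_geometry <- function(V_R = 600, aspect_ratio = 6,
                             fill_fraction = 0.95) {
  stopifnot(V_R > 0, aspect_ratio > 0)
  if (fill_fraction <= 0 || fill_fraction > 1)
    .scp_stop("invalid_config", "fill_fraction must be in (0, 1]")
  D_R <- (4 * V_R / (aspect_ratio * pi))^(1 / 3)
  H_R <- aspect_ratio * D_R
  structure(list(V_R = V_R, aspect_ratio = aspect_ratio,
                 fill_fraction = fill_fraction,
                 D_R = D_R, H_R = H_R,
                 A_cross = pi / 4 * D_R^2,
                 H_aerated = fill_fraction * H_R,
                 V_aerated = fill_fraction * V_R),
            class = "scp_geometry")
}

.default_correlations <- function() {
  list(kla_a = 0.32, kla_b = 0.7, kla_theta = 1.022,
       holdup_a = 0.6, holdup_b = 0.7,
       coalescence_factor = 1,
       pressure_mean = "log")  # "log", "arithmetic" or "top"
}

#' Volumetric gas-liquid mass-transfer coefficient kLa
#'
#' Coalescing-broth correlation for a heterogeneous-regime bubble column,
#' `kLa_O2 = a * vsG_mean^b * theta^(T - 20)` in 1/s (returned in 1/h), with
#' defaults a = 0.32, b = 0.7, theta = 1.022.  For CO2 the O2 value is
#' corrected by the square root of the diffusivity ratio.  The correlation
#' is validated for 0.04-0.30 m/s; outside that window a warning is issued
#' but the value is still returned.
#'
#' @param vsG_mean mean superficial gas velocity, m/s.
#' @param T broth temperature, degrees Celsius.
#' @param gas `"O2"` or `"CO2"`.
#' @param props an [physical_properties()] object (diffusivity ratio).
#' @param correlations list of correlation constants (see
#'   [scp_config()]`$correlations`), including the coalescence factor
#'   multiplier (1 = coalescing broth).
#' @return kLa in 1/h.
#' @examples
#' kla(0.30, 30)  # 617 1/h
#' kla(0.04, 30)  # 150 1/h
#' @export
kla <- function(vsG_mean, T, gas = c("O2", "CO2"),
                props = physical_properties(),
                correlations = .default_correlations()) {
  gas <- match.arg(gas)
  if (!is.finite(vsG_mean) || vsG_mean <= 0)
    .scp_stop("domain_error", "vsG_mean must be positive")
  if (vsG_mean < 0.04 - 1e-9 || vsG_mean > 0.30 + 1e-9)
    .scp_warn("correlation_range", sprintf(
      "vsG_mean = %.3g m/s outside the 0.04-0.30 m/s validity window of the kLa correlation",
      vsG_mean))
  co <- correlations
  v <- co$kla_a * vsG_mean^co$kla_b * co$kla_theta^(T - 20) *
    co$coalescence_factor * 3600
  if (gas == "CO2")
    v <- v * sqrt(props$diffusivity[["CO2"]] / props$diffusivity[["O2"]])
  v
}

#' Gas hold-up of the aerated broth
#'
#' `eps_G = a * vsG_mean^b` (defaults 0.6, 0.7), capped below 1.
#'
#' @inheritParams kla
#' @return Gas hold-up, dimensionless in `[0, 1)`.
#' @examples
#' gas_holdup(0.30)  # 0.26
#' @export
gas_holdup <- function(vsG_mean, correlations = .default_correlations()) {
  stopifnot(is.finite(vsG_mean), vsG_mean >= 0)
  min(correlations$holdup_a * vsG_mean^correlations$holdup_b, 1 - 1e-9)
}

#' Superficial gas velocity from a molar gas flow (and its inverse)
#'
#' Ideal-gas conversion: `vsG = FG_N R T / (p A_cross)`.
#'
#' @param FG_N molar gas flow, mol/h.
#' @param p absolute pressure, bar.
#' @param T temperature, K.
#' @param geometry an [reactor_geometry()] object.
#' @return Superficial velocity in m/s (`superficial_velocity`) or molar
#'   flow in mol/h (`molar_gas_flow`); the two are exact inverses.
#' @export
superficial_velocity <- function(FG_N, p, T, geometry = reactor_geometry()) {
  if (!is.finite(p) || p <= 0)
    .scp_stop("domain_error", "pressure must be positive")
  stopifnot(FG_N >= 0, T > 0)
  (FG_N / 3600) * .R_GAS * T / (p * 1e5) / geometry$A_cross
}

#' @rdname superficial_velocity
#' @param vsG superficial gas velocity, m/s.
#' @export
molar_gas_flow <- function(vsG, p, T, geometry = reactor_geometry()) {
  if (!is.finite(p) || p <= 0)
    .scp_stop("domain_error", "pressure must be positive")
  stopifnot(vsG >= 0, T > 0)
  vsG * p * 1e5 * geometry$A_cross / (.R_GAS * T) * 3600
}

#' Logarithmic mean of two positive values
#'
#' `(a - b)/log(a/b)`, with the continuous limit `a` as `a -> b`.  Used for
#' the column-average superficial gas velocity and total pressure.
#'
#' @param a,b positive values.
#' @return The log mean, always between `min(a, b)` and `max(a, b)`.
#' @export
log_mean <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    .scp_stop("domain_error", "log_mean requires positive finite inputs")
  if (abs(a - b) < 1e-12 * max(a, b)) return(a)
  (a - b) / log(a / b)
}

#' Absolute pressure at the column bottom
#'
#' Top pressure plus the hydrostatic head of the aerated liquid column:
#' `p_bot = p_top + rho_L (1 - eps_G) g H_aerated / 1e5` bar.
#'
#' @param p_top absolute overhead pressure, bar.
#' @param eps_G gas hold-up.
#' @param geometry an [reactor_geometry()] object.
#' @param rho_L ungassed liquid density, kg/m3.
#' @return Bottom pressure in bar, always `>= p_top`.
#' @export
bottom_pressure <- function(p_top, eps_G, geometry = reactor_geometry(),
                            rho_L = 1000) {
  stopifnot(p_top > 0, eps_G >= 0, eps_G < 1)
  p_top + rho_L * (1 - eps_G) * .G_ACC * geometry$H_aerated / 1e5
}

#' Gas-to-liquid transfer rate of a sparingly soluble gas
#'
#' `N = kLa (K_H y p_eff - C_bulk)`: the driving force is the equilibrium
#' concentration at the bubble surface (off-gas mole fraction, since the gas
#' phase is taken as ideally mixed, at the effective column pressure) minus
#' the bulk dissolved concentration.  Positive values are gas-to-liquid;
#' negative values (CO2 leaving the broth) are legal.
#'
#' @param gas gas species identifier.
#' @param y_out off-gas mole fraction of the gas.
#' @param p_eff effective (column-averaged) absolute pressure, bar.
#' @param C_bulk bulk dissolved concentration, mol/kg.
#' @param kla_val volumetric transfer coefficient, 1/h.
#' @param T temperature, K.
#' @param props an [physical_properties()] object.
#' @return Transfer rate, mol/(kg_L h).
#' @export
transfer_rate <- function(gas, y_out, p_eff, C_bulk, kla_val, T,
                          props = physical_properties()) {
  stopifnot(y_out >= 0, y_out <= 1, kla_val > 0)
  kla_val * (henry_coefficient(gas, T, props) * y_out * p_eff - C_bulk)
}

#' Evaporation rate of water into the off-gas
#'
#' Water is assumed at equilibrium between gas and liquid: the off-gas water
#' fraction is `y_W = p_W_sat(T)/p` (evaluated at the top pressure, where
#' the off-gas leaves), and the evaporation rate is
#' `-N_W = y_W FG_N_out / M_L`.
#'
#' @param FG_N_out molar off-gas flow, mol/h.
#' @param p_top absolute top pressure, bar.
#' @param T temperature, K.
#' @param M_L liquid mass, kg.
#' @param props an [physical_properties()] object.
#' @return List with `N_W` (mol/(kg_L h), negative = liquid to gas) and
#'   `y_W` (off-gas water mole fraction).
#' @export
evaporation_rate <- function(FG_N_out, p_top, T, M_L,
                             props = physical_properties()) {
  stopifnot(FG_N_out >= 0, M_L > 0)
  psat <- water_vapor_pressure(T, props)
  if (p_top <= psat)
    .scp_stop("saturation_error", sprintf(
      "total pressure %.3g bar does not exceed the water vapor pressure %.3g bar",
      p_top, psat))
  y_W <- psat / p_top
  list(N_W = -y_W * FG_N_out / M_L, y_W = y_W)
}
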