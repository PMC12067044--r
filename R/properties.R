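#' Temperature-dependent physical properties of the broth and dissolved gases
#'
#' Bundles the physical constants used throughout the model: Henry solubility
#' coefficients with van't Hoff temperature dependence, liquid-film
#' diffusivities, liquid density and heat capacity, the latent heat of water,
#' the metabolic heat released per mole of O2, the overall heat-transfer
#' coefficient of the cooling exchangers, and Antoine constants for the water
#' vapor pressure.
#'
#' Henry reference values are compilation (Sander-type) constants for pure
#' water at 298.15 K, in mol/(kg bar).  The O2 value (1.2e-3) is consistent
#' with an air-saturation concentration of 0.23 mmol/kg at 30 C, i.e. with a
#' dissolved-O2 setpoint of 0.069 mmol/kg being 30% of air saturation.
#' Dissolved CO2 is treated as molecular CO2 only; at pH 6 the
#' bicarbonate/carbonate speciation is negligible and is not modelled.
#'
#' @param henry_ref named numeric, solubility at `T_ref` in mol/(kg bar).
#' @param henry_vant_hoff named numeric, -d(ln K_H)/d(1/T) in K (positive for
#'   gases whose solubility falls with temperature).
#' @param diffusivity named numeric, liquid-film diffusivities in m2/s; only
#'   the CO2/O2 ratio enters the model (square-root correction of kLa).
#' @param rho_L ungassed liquid density, kg/m3.
#' @param cp liquid heat capacity, kJ/(kg K).
#' @param dH_evap molar latent heat of water, kJ/mol (30 C literature value).
#' @param heat_per_O2 heat released per mole O2 consumed, kJ/mol.
#' @param U overall heat-transfer coefficient of the exchangers, kW/(m2 K).
#' @param antoine Antoine constants `A`, `B`, `C` for water, with pressure in
#'   mmHg and temperature in degrees Celsius.
#' @param T_ref reference temperature of `henry_ref`, K.
#' @return An object of class `scp_properties`.
#' @examples
#' props <- physical_properties()
#' henry_coefficient("O2", 303.15, props)
#' @export
physical_properties <- function(henry_ref = c(O2 = 1.2e-3, CO2 = 3.3e-2,
                                              N2 = 6.4e-4, H2 = 7.8e-4,
                                              CH4 = 1.57e-3, CO = 9.7e-4),
                                henry_vant_hoff = c(O2 = 1500, CO2 = 2400,
                                                    N2 = 1300, H2 = 500,
                                                    CH4 = 1900, CO = 1300),
                                diffusivity = c(O2 = 2.10e-9, CO2 = 1.92e-9),
                                rho_L = 1000,
                                cp = 4.18,
                                dH_evap = 43.5,
                                heat_per_O2 = 460,
                                U = 1.4,
                                antoine = c(A = 8.07131, B = 1730.63,
                                            C = 233.426),
                                T_ref = 298.15) {
  stopifnot(all(henry_ref > 0), all(diffusivity > 0), rho_L > 0, cp > 0,
            dH_evap > 0, heat_per_O2 > 0, U > 0)
  if (!setequal(names(henry_ref), names(henry_vant_hoff)))
    .scp_stop("invalid_properties",
              "henry_ref and henry_vant_hoff must name the same gases")
  structure(list(henry_ref = henry_ref,
                 henry_vant_hoff = henry_vant_hoff,
                 diffusivity = diffusivity,
                 rho_L = rho_L, cp = cp, dH_evap = dH_evap,
                 heat_per_O2 = heat_per_O2, U = U,
                 antoine = antoine, T_ref = T_ref),
            class = "scp_properties")
}

.check_T_range <- function(T) {
  if (!is.finite(T) || T <= 273 || T > 373.15 + 1e-6)
    .scp_stop("domain_error",
              sprintf("temperature %.2f K outside the supported 273-373 K range", T))
}

#' Henry solubility coefficient of a gas in water
#'
#' Van't Hoff temperature correction of the reference compilation value:
#' `K_H(T) = K_H(T_ref) * exp(C * (1/T - 1/T_ref))`.  Solubility decreases
#' with temperature for all supported gases.
#'
#' @param gas one of `"O2"`, `"CO2"`, `"N2"`, `"H2"`, `"CH4"`, `"CO"`.
#' @param T temperature, K (273-373).
#' @param props an [physical_properties()] object.
#' @return Solubility in mol/(kg bar).
#' @examples
#' henry_coefficient("O2", 303.15)   # ~1.10e-3 mol/(kg bar)
#' @export
henry_coefficient <- function(gas, T, props = physical_properties()) {
  if (!gas %in% names(props$henry_ref))
    .scp_stop("unknown_gas", sprintf("unsupported gas species '%s'", gas))
  .check_T_range(T)
  unname(props$henry_ref[[gas]] *
           exp(props$henry_vant_hoff[[gas]] * (1 / T - 1 / props$T_ref)))
}

#' Saturated vapor pressure of water
#'
#' Antoine correlation (constants in `props$antoine`, mmHg / Celsius form),
#' converted to bar.
#'
#' @param T temperature, K (273-373).
#' @inheritParams henry_coefficient
#' @return Pressure in bar; strictly increasing with temperature.
#' @examples
#' water_vapor_pressure(303.15)  # ~0.042 bar
#' @export
water_vapor_pressure <- function(T, props = physical_properties()) {
  .check_T_range(T)
  a <- props$antoine
  Tc <- T - 273.15
  p_mmHg <- 10^(a[["A"]] - a[["B"]] / (a[["C"]] + Tc))
  p_mmHg * 1.01325 / 760
}
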