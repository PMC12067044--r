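# Heat balance, external cooling-loop sizing, and the cell-stress profile
# of the cooling loop.

#' Steady-state heat balance of the fermentation
#'
#' `0 = Q_r - Q_evap - Q_cool`: the heat of reaction is proportional to the
#' O2 consumption (460 kJ per mole O2 for aerobic heterotrophic growth),
#' water evaporation into the off-gas withdraws latent heat, and the
#' remainder must be removed by cooling.  Feed streams enter at fermentation
#' temperature and gas compression heat is neglected.
#'
#' @param sol an [solve_operating_point()] solution.
#' @return List with `Q_r`, `Q_evap`, `Q_cool` (kW) and `specific_load`
#'   (W per kg of liquid, `= heat_per_O2 * N_O2`).
#' @examples
#' \donttest{
#' heat_balance(solve_operating_point(vsG_mean = 0.30))$specific_load # ~140 W/kg
#' }
#' @export
heat_balance <- function(sol) {
  props <- .cfg_properties(sol$config)
  Q_r <- props$heat_per_O2 * (-sol$R_O2) / 3600          # kJ/mol * mol/h -> kW
  Q_evap <- sol$FG_out * sol$y_W_out * props$dH_evap / 3600
  list(Q_r = Q_r, Q_evap = Q_evap, Q_cool = Q_r - Q_evap,
       specific_load = props$heat_per_O2 * 1000 * sol$N_O2 / 3600)
}

#' Size the external cooling loop
#'
#' The required area follows from `Q_cool = U A_cool dT_lm`; the number of
#' parallel shell-and-tube exchangers from the largest catalogue unit
#' (`cooling$unit_area_max`, 430 m2), with the resulting per-unit area
#' reported (close to the 400 m2 nominal design value at the base case).
#' The broth flow through the loop follows from `Q_cool = F_cool cp
#' dT_loop`.  The area an internal helical coil could provide is computed
#' from three rules - pipe diameter `D_R/30`, pitch twice the pipe
#' diameter, number of turns equal to the aerated height over diameter plus
#' pitch - and quantifies why an external loop is needed.
#'
#' @param sol an [solve_operating_point()] solution.
#' @return Object of class `scp_cooling` with heat duties (kW), `A_cool`
#'   (m2), `n_exchangers`, `area_per_unit` (m2), `F_cool` (kg/s),
#'   `passes_per_hour` (1/h), `coil_area_available` (m2), the tube
#'   geometry, `n_tubes` per unit (catalogue count scaled to the design
#'   area by default) and the single-pass `tube_velocity` (m/s).
#' @export
size_cooling_system <- function(sol) {
  cfg <- sol$config
  cl <- cfg$cooling
  props <- .cfg_properties(cfg)
  geom <- .cfg_geometry(cfg)
  hb <- heat_balance(sol)
  Q <- hb$Q_cool
  if (Q < 0) .scp_stop("domain_error", "negative cooling duty")

  A_cool <- Q / (props$U * cl$dT_lm)
  n_ex <- if (A_cool == 0) 0L else as.integer(ceiling(A_cool / cl$unit_area_max - 1e-12))
  F_cool <- Q / (props$cp * cl$dT_loop)                  # kg/s

  d_pipe <- geom$D_R / cl$coil_pipe_ratio
  turns <- geom$H_aerated / (3 * d_pipe)                 # pipe + 2x pitch
  coil_area <- turns * (pi * d_pipe) * (pi * geom$D_R)

  n_tubes <- cl$tubes_per_unit
  if (isTRUE(cl$scale_tubes_to_design))
    n_tubes <- cl$tubes_per_unit * cl$unit_area_design / cl$unit_area_max
  tube_area <- pi / 4 * cl$tube_id^2
  v_tube <- if (n_ex > 0)
    F_cool / props$rho_L / (n_ex * n_tubes * tube_area) else 0

  structure(list(
    Q_r = hb$Q_r, Q_evap = hb$Q_evap, Q_cool = Q,
    specific_load = hb$specific_load,
    A_cool = A_cool, n_exchangers = n_ex,
    area_per_unit = if (n_ex > 0) A_cool / n_ex else 0,
    F_cool = F_cool,
    passes_per_hour = F_cool * 3600 / sol$M_L,
    coil_area_available = coil_area,
    coil_area_per_volume = coil_area / (sol$M_L / props$rho_L),
    n_tubes = n_tubes, tube_id = cl$tube_id,
    tube_length = cl$tube_length,
    tube_velocity = v_tube,                              # single-pass, m/s
    dT_lm = cl$dT_lm, dT_loop = cl$dT_loop, U = props$U),
    class = "scp_cooling")
}

#' @export
print.scp_cooling <- function(x, ...) {
  cat(sprintf(paste0(
    "Cooling design: Q_r = %.1f MW, Q_evap = %.2f MW, Q_cool = %.1f MW\n",
    "  A_cool = %.0f m2 in %d exchangers (%.0f m2 each); internal coil could give %.0f m2\n",
    "  loop flow %.0f kg/s (%.1f passes/h); single-pass tube velocity %.2f m/s\n"),
    x$Q_r / 1000, x$Q_evap / 1000, x$Q_cool / 1000,
    x$A_cool, x$n_exchangers, x$area_per_unit, x$coil_area_available,
    x$F_cool, x$passes_per_hour, x$tube_velocity))
  invisible(x)
}

#' Cell-stress profile of the cooling loop
#'
#' Quantifies the three stress sources cells face in the external loop:
#' the shear stress in the exchanger tubes and at the circulation pump, and
#' the race between the loop residence time and the times in which cells
#' deplete the dissolved O2 and substrate (zero-order consumption at the
#' bulk rates, no transfer inside the loop).
#'
#' The tube wall shear uses the simple estimator `mu v / d`; the laminar
#' `8 mu v / d` variant is reported alongside.  The pump shear is the
#' blade-tip velocity gradient across the tip-casing clearance.
#'
#' @param design an [size_cooling_system()] object.
#' @param sol the corresponding [solve_operating_point()] solution.
#' @param passes_in_tubes number of tube-side passes (raises the velocity
#'   proportionally).
#' @param extra_piping loop piping length outside the exchanger, m.
#' @param rpm_range pump impeller speed range, 1/min.
#' @param impeller_diameter axial pump impeller diameter, m.
#' @param clearance blade-tip to casing clearance, m.
#' @return Object of class `scp_stress` with `tube_velocity` (m/s),
#'   `wall_shear` and `wall_shear_laminar` (Pa), `pump_shear` (Pa, range),
#'   `t_O2_depletion` and `t_S_depletion` (s), `t_loop_residence` (s).
#' @export
stress_profile <- function(design, sol, passes_in_tubes = 1,
                           extra_piping = 10, rpm_range = c(60, 600),
                           impeller_diameter = 0.6, clearance = 3e-4) {
  if (design$tube_velocity <= 0)
    .scp_stop("degenerate_design", "cooling design has zero tube velocity")
  mu <- sol$config$cooling$viscosity
  v <- design$tube_velocity * passes_in_tubes
  tip_speed <- pi * impeller_diameter * rpm_range / 60
  q_S <- abs(sol$stoichiometry$qS)                       # mol_S/(mol_x h)
  r_S <- q_S * sol$C_x_molar                             # mol/(kg h)
  structure(list(
    tube_velocity = v,
    wall_shear = mu * v / design$tube_id,
    wall_shear_laminar = 8 * mu * v / design$tube_id,
    pump_shear = mu * tip_speed / clearance,
    rpm_range = rpm_range,
    t_O2_depletion = sol$C_O2 / sol$N_O2 * 3600,
    t_S_depletion = sol$C_S / r_S * 3600,
    t_loop_residence = (passes_in_tubes * design$tube_length + extra_piping) / v,
    viscosity = mu),
    class = "scp_stress")
}

#' @export
print.scp_stress <- function(x, ...) {
  cat(sprintf(paste0(
    "Cooling-loop stress: tube velocity %.2f m/s, wall shear %.2f Pa\n",
    "  pump shear %.0f-%.0f Pa (%.0f-%.0f rpm)\n",
    "  depletion times: O2 %.2f s, substrate %.1f s; loop residence %.1f s\n"),
    x$tube_velocity, x$wall_shear,
    x$pump_shear[1], x$pump_shear[2], x$rpm_range[1], x$rpm_range[2],
    x$t_O2_depletion, x$t_S_depletion, x$t_loop_residence))
  invisible(x)
}
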