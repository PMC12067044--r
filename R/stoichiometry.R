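#' Molecular formula of a CHON compound
#'
#' @param C,H,O,N atom counts per mole (non-negative, fractional allowed as
#'   in the standard biomass unit-carbon formula CH1.8O0.5N0.2).
#' @return Object of class `scp_formula` with fields `C`, `H`, `O`, `N` and
#'   `molar_mass` (g/mol).
#' @seealso [parse_chemical_formula()], [degree_of_reduction()]
#' @export
molecular_formula <- function(C = 0, H = 0, O = 0, N = 0) {
  counts <- c(C = C, H = H, O = O, N = N)
  if (any(!is.finite(counts)) || any(counts < 0) || all(counts == 0))
    .scp_stop("invalid_formula",
              "atom counts must be non-negative and not all zero")
  structure(list(C = C, H = H, O = O, N = N,
                 molar_mass = sum(counts * .ATOMIC_MASS)),
            class = "scp_formula")
}

#' Parse a formula string such as "C2H6O" or "CH1.8O0.5N0.2"
#'
#' Only C, H, O and N are supported; counts may be decimal.
#'
#' @param x formula string.
#' @return An `scp_formula` object.
#' @export
parse_chemical_formula <- function(x) {
  if (inherits(x, "scp_formula")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([CHON])([0-9]*\\.?[0-9]*)", x)[[1]]
  parts <- regmatches(x, gregexpr("([CHON])([0-9]*\\.?[0-9]*)", x))[[1]]
  if (length(parts) == 0 || sum(nchar(parts)) != nchar(x))
    .scp_stop("invalid_formula",
              sprintf("cannot parse '%s' as a CHON formula", x))
  counts <- c(C = 0, H = 0, O = 0, N = 0)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substring(p, 2)
    counts[[el]] <- counts[[el]] + if (nzchar(n)) as.numeric(n) else 1
  }
  molecular_formula(counts[["C"]], counts[["H"]], counts[["O"]], counts[["N"]])
}

#' Degree of reduction of a CHON compound
#'
#' Available electrons per mole relative to CO2, H2O and NH3:
#' `gamma = 4 C + H - 2 O - 3 N`.  Ethanol gives 12, glucose 24, standard
#' biomass CH1.8O0.5N0.2 gives 4.2.
#'
#' @param formula an `scp_formula` or formula string.
#' @return Degree of reduction, mol electrons / mol.
#' @export
degree_of_reduction <- function(formula) {
  f <- parse_chemical_formula(formula)
  4 * f$C + f$H - 2 * f$O - 3 * f$N
}

#' Microbial kinetic parameters for chemostat growth
#'
#' Herbert-Pirt substrate partitioning with Monod uptake kinetics.  If
#' `qS_max` is `NULL` it is derived from the Herbert-Pirt relation evaluated
#' at `mu_max`: `qS_max = mu_max / Y_xs_max(molar) + m_S`, which for the
#' ethanol defaults gives 0.191 mol_S/(mol_x h).
#'
#' @param mu_max maximum specific growth rate, 1/h.
#' @param Y_xs_max maximum biomass yield on substrate, g_x/g_S.
#' @param m_S maintenance coefficient, mol_S/(mol_x h).
#' @param K_S substrate affinity constant, mol/kg_L.
#' @param qS_max maximum specific substrate uptake, mol_S/(mol_x h), or
#'   `NULL` to derive it from `mu_max`.
#' @return Object of class `scp_kinetics`.
#' @export
kinetic_parameters <- function(mu_max = 0.22, Y_xs_max = 0.63, m_S = 0.005,
                               K_S = 5e-4, qS_max = NULL) {
  stopifnot(mu_max > 0, Y_xs_max > 0, m_S >= 0, K_S > 0)
  structure(list(mu_max = mu_max, Y_xs_max = Y_xs_max, m_S = m_S,
                 K_S = K_S, qS_max = qS_max),
            class = "scp_kinetics")
}

# molar maximum yield, mol_x/mol_S, from the mass yield
.yield_molar <- function(params, biomass, substrate) {
  params$Y_xs_max * substrate$molar_mass / biomass$molar_mass
}

.qS_max <- function(params, biomass, substrate) {
  if (!is.null(params$qS_max)) return(params$qS_max)
  params$mu_max / .yield_molar(params, biomass, substrate) + params$m_S
}

#' Specific substrate uptake and residual concentration at a growth rate
#'
#' The Herbert-Pirt relation gives the uptake
#' `-qS = mu / Y_xs_max(molar) + m_S`; inverting the Monod hyperbola then
#' yields the residual substrate concentration that sustains that uptake,
#' `C_S = K_S (-qS) / (qS_max - (-qS))`.
#'
#' @param mu specific growth rate (= dilution rate at steady state), 1/h;
#'   must satisfy `0 <= mu < mu_max`.
#' @param params an [kinetic_parameters()] object.
#' @param biomass,substrate `scp_formula` objects (or strings); defaults are
#'   standard biomass and ethanol.
#' @return List with `qS` (signed, negative = consumption, mol_S/(mol_x h)),
#'   `qS_max`, and `residual_CS` (mol/kg_L).
#' @examples
#' substrate_uptake(0.15, kinetic_parameters())  # -qS/mu = 0.88, CS = 1.1 mmol/kg
#' @export
substrate_uptake <- function(mu, params = kinetic_parameters(),
                             biomass = parse_chemical_formula("CH1.8O0.5N0.2"),
                             substrate = parse_chemical_formula("C2H6O")) {
  biomass <- parse_chemical_formula(biomass)
  substrate <- parse_chemical_formula(substrate)
  if (!is.finite(mu) || mu < 0)
    .scp_stop("domain_error", "growth rate must be non-negative")
  if (mu >= params$mu_max)
    .scp_stop("washout", sprintf(
      "mu = %.3g 1/h >= mu_max = %.3g 1/h: washout, no steady state",
      mu, params$mu_max))
  qS_mag <- mu / .yield_molar(params, biomass, substrate) + params$m_S
  qS_max <- .qS_max(params, biomass, substrate)
  if (qS_mag >= qS_max)
    .scp_stop("washout", sprintf(
      "required uptake %.3g exceeds qS_max %.3g mol_S/(mol_x h)",
      qS_mag, qS_max))
  list(qS = -qS_mag, qS_max = qS_max,
       residual_CS = params$K_S * qS_mag / (qS_max - qS_mag))
}

#' Process-reaction stoichiometry at a given growth rate
#'
#' Builds the growth reaction per mole of biomass formed.  The substrate
#' coefficient follows from Herbert-Pirt uptake (`nu_S = qS/mu`); the O2,
#' CO2, H2O and NH3 coefficients are obtained by solving the carbon,
#' hydrogen, nitrogen and electron (degree-of-reduction) balances as a
#' linear system.  The oxygen element balance is redundant and is used as a
#' closure check, stored in `closure_residual`.
#'
#' @inheritParams substrate_uptake
#' @return Object of class `scp_stoichiometry` with fields `mu`,
#'   `coefficients` (named: biomass, substrate, O2, CO2, H2O, NH3;
#'   consumption negative, biomass = +1), `RQ` (respiratory quotient
#'   `q_CO2 / -q_O2`), `Y_xs` (realized yield g_x/g_S), `qS`, `qS_max`,
#'   `residual_CS`, `closure_residual`, and the two formulas.
#' @examples
#' process_reaction(0.15)  # Ethanol -0.88, O2 -1.59, CO2 0.76, RQ 0.48
#' @export
process_reaction <- function(mu, params = kinetic_parameters(),
                             biomass = parse_chemical_formula("CH1.8O0.5N0.2"),
                             substrate = parse_chemical_formula("C2H6O")) {
  biomass <- parse_chemical_formula(biomass)
  substrate <- parse_chemical_formula(substrate)
  if (!is.finite(mu) || mu <= 0)
    .scp_stop("domain_error", "process_reaction requires mu > 0")
  up <- substrate_uptake(mu, params, biomass, substrate)
  nu_S <- up$qS / mu  # negative

  # unknown coefficients: O2, CO2, H2O, NH3 (signed)
  # rows: C, H, N, electron balances
  A <- rbind(C = c(0, 1, 0, 0),
             H = c(0, 0, 2, 3),
             N = c(0, 0, 0, 1),
             e = c(-4, 0, 0, 0))
  known <- function(el) biomass[[el]] + nu_S * substrate[[el]]
  b <- -c(known("C"), known("H"), known("N"),
          degree_of_reduction(biomass) + nu_S * degree_of_reduction(substrate))
  nu <- solve(A, b)
  coef <- c(biomass = 1, substrate = nu_S,
            O2 = nu[[1]], CO2 = nu[[2]], H2O = nu[[3]], NH3 = nu[[4]])

  # redundant O balance, relative closure
  o_res <- known("O") + 2 * coef[["O2"]] + 2 * coef[["CO2"]] + coef[["H2O"]]
  o_scale <- max(abs(c(2 * coef[["O2"]], 2 * coef[["CO2"]], coef[["H2O"]])))
  structure(list(mu = mu,
                 coefficients = coef,
                 RQ = coef[["CO2"]] / abs(coef[["O2"]]),
                 Y_xs = (mu / -up$qS) * biomass$molar_mass / substrate$molar_mass,
                 qS = up$qS, qS_max = up$qS_max,
                 residual_CS = up$residual_CS,
                 closure_residual = abs(o_res) / o_scale,
                 biomass = biomass, substrate = substrate,
                 params = params),
            class = "scp_stoichiometry")
}

#' @export
print.scp_stoichiometry <- function(x, ...) {
  cat(sprintf("Process reaction at mu = %.3g 1/h (per mol biomass):\n", x$mu))
  print(round(x$coefficients, 4))
  cat(sprintf("RQ = %.3f   Y_x/S = %.3f g/g   residual C_S = %.3g mol/kg\n",
              x$RQ, x$Y_xs, x$residual_CS))
  invisible(x)
}
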