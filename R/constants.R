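# Internal physical and chemical constants.

# molar gas constant, J/(mol K)
.R_GAS <- 8.314462618

# standard gravity, m/s^2
.G_ACC <- 9.80665

# IUPAC atomic masses, g/mol
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

# electrons available per atom relative to CO2/H2O/NH3 (NH3 nitrogen reference)
.GAMMA_ATOM <- c(C = 4, H = 1, O = -2, N = -3)

# molar masses of the fixed species in the gas/liquid balances, g/mol
.M_O2  <- 2 * .ATOMIC_MASS[["O"]]
.M_CO2 <- .ATOMIC_MASS[["C"]] + 2 * .ATOMIC_MASS[["O"]]
.M_H2O <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]
.M_NH3 <- 3 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["N"]]
.M_N2  <- 2 * .ATOMIC_MASS[["N"]]

# condition constructor used by all modules; `class` gets an "scp_" prefix
# so callers can test errors by class.
.scp_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("scp_", class), "scp_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

.scp_warn <- function(class, msg) {
  warning(structure(
    class = c(paste0("scp_", class), "scp_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
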