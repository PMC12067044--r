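# The staged gas/liquid solver and its invariants.

sol30 <- solve_base(0.30)
sol04 <- solve_base(0.04)

test_that("the gas-phase residual brackets exactly one root", {
  stoich <- process_reaction(0.15)
  vt <- sol30$vsG_top
  vb <- seq(0.9 * sol30$vsG_bot, 1.5 * sol30$vsG_bot, length.out = 50)
  r <- vapply(vb, function(v)
    suppressWarnings(as.numeric(gas_phase_residual(v, vt, stoich))),
    numeric(1))
  expect_true(all(is.finite(r)))
  sign_changes <- sum(diff(sign(r)) != 0)
  expect_equal(sign_changes, 1)
  # continuity: no jumps larger than the local trend
  expect_lt(max(abs(diff(r))), 0.2)
})

test_that("the converged point has a vanishing residual", {
  stoich <- process_reaction(0.15)
  r <- suppressWarnings(
    gas_phase_residual(sol30$vsG_bot, sol30$vsG_top, stoich))
  expect_lt(abs(as.numeric(r)) / sol30$N_O2, 1e-9)
})

test_that("all ten material balances close on the stored solution", {
  for (sol in list(sol30, sol04,
                   solve_base(0.30, base_config(
                     operation = list(y_O2_in = 0.21))))) {
    res <- table2_residuals(sol)
    expect_lt(max(res), 1e-9)
  }
})

test_that("gas-side conservation holds to solver tolerance", {
  lhs <- sol30$FG_in - sol30$FG_out
  rhs <- (sol30$N_O2 + sol30$N_CO2 + sol30$N_W) * sol30$M_L
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("biomass concentration is proportional to the O2 transfer rate", {
  nuO2 <- abs(sol30$stoichiometry$coefficients[["O2"]])
  expect_equal(sol30$C_x_molar * sol30$config$operation$D * sol30$M_L,
               -sol30$R_O2 / nuO2, tolerance = 1e-12)
})

test_that("the staged solver agrees with a simultaneous solve of all balances", {
  skip_if_not_installed("pracma")
  for (v in c(0.05, 0.15, 0.30)) {
    staged <- solve_base(v)
    sim <- simultaneous_solve(v)
    expect_equal(staged$N_O2, sim$N_O2, tolerance = 1e-6,
                 label = paste("N_O2 at", v))
    expect_equal(staged$C_x, sim$C_x, tolerance = 1e-6,
                 label = paste("C_x at", v))
  }
})

test_that("velocity can be specified at the top or as the column mean", {
  by_mean <- solve_base(0.20)
  by_top <- solve_operating_point(scp_config(), vsG_top = by_mean$vsG_top)
  expect_equal(by_top$vsG_mean, 0.20, tolerance = 1e-9)
  expect_equal(by_top$N_O2, by_mean$N_O2, tolerance = 1e-9)
})

test_that("the converged base point reproduces the reference operating window", {
  expect_equal(sol30$N_O2, 1.09, tolerance = 0.05)
  expect_equal(sol30$O2_utilization, 27, tolerance = 0.05)
  expect_equal(sol30$C_x, 114, tolerance = 0.05)
  expect_equal(sol30$y_O2_out, 0.82, tolerance = 0.05)
  expect_equal(sol30$C_CO2 * 1000, 9.6, tolerance = 0.05)
  expect_equal(sol04$N_O2, 0.24, tolerance = 0.05)
  expect_equal(sol04$O2_utilization, 48, tolerance = 0.05)
  expect_equal(sol04$C_CO2 * 1000, 20, tolerance = 0.05)
  expect_equal(sol04$y_O2_out, 0.67, tolerance = 0.05)
})

test_that("liquid-side flows close the plant mass balance", {
  expect_equal(sol30$F_L_out / 1000, 63, tolerance = 0.05)     # t/h
  expect_equal(sol30$C_S_in, 224, tolerance = 0.05)            # g/kg
  expect_equal(sol30$F_S_feed / 1000, 53, tolerance = 0.05)    # t/h
  expect_equal(sol30$F_N_feed / 1000, 5, tolerance = 0.10)     # t/h
  expect_gt(sol30$ethanol_utilization, 99.9)
  r_S <- abs(sol30$stoichiometry$qS) * sol30$C_x_molar
  expect_equal(r_S, 0.605, tolerance = 0.05)                   # mol/(kg h)
})

test_that("sweep shows the documented monotone trends", {
  sw <- sweep_operating_points(scp_config(), seq(0.04, 0.30, by = 0.02))
  tab <- sw$table
  expect_equal(nrow(tab), 14)
  expect_length(sw$failures, 0)
  expect_true(all(diff(tab$N_O2) > 0))
  expect_true(all(diff(tab$O2_utilization) < 0))
  expect_true(all(diff(tab$eps_G) > 0))
  expect_true(all(diff(tab$M_L) < 0))
  expect_true(all(diff(tab$kla_O2) > 0))
  # liquid mass shrinks by about a fifth over the regime window
  expect_equal(100 * (1 - min(tab$M_L) / max(tab$M_L)), 21, tolerance = 0.05)
  # off-gas stays O2-rich throughout
  expect_true(all(tab$y_O2_out > 0.66 & tab$y_O2_out < 0.83))
})

test_that("carbon-balance error is positive and fades with gas velocity", {
  sw <- sweep_operating_points(scp_config(), c(0.04, 0.10, 0.20, 0.30))
  err <- sw$table$carbon_balance_error
  expect_true(all(err > 0))
  expect_true(all(diff(err) < 0))
  expect_equal(err[4], 0.1, tolerance = 0.3)
  # forcing the dissolved CO2 to zero removes the error
  s <- sol30; s$C_CO2 <- 0
  expect_equal(carbon_balance_error(s), 0)
})

test_that("air sparging transfers far less O2 than pure O2", {
  air <- solve_base(0.30, base_config(operation = list(y_O2_in = 0.21)))
  expect_lt(air$O2_utilization, sol30$O2_utilization)
  expect_lt(air$N_O2, sol30$N_O2)
  expect_gt(sol30$R_x_kg / air$R_x_kg, 3)
  # N2 passes through unconsumed
  expect_equal(air$FG_in * 0.79, air$FG_out * air$y_N2_out,
               tolerance = 1e-9)
})

test_that("an unreachable dissolved-O2 setpoint has no steady state", {
  # a setpoint above the saturation concentration makes the transfer
  # driving force negative at every off-gas composition
  cfg <- base_config(operation = list(C_O2_set = 5e-3))
  expect_error(suppressWarnings(solve_operating_point(cfg, vsG_mean = 0.30)),
               class = "scp_error")
})

test_that("solutions are bit-reproducible for identical configurations", {
  a <- solve_base(0.17)
  b <- solve_base(0.17)
  expect_identical(a$N_O2, b$N_O2)
  expect_identical(a$C_x, b$C_x)
  expect_identical(a$vsG_bot, b$vsG_bot)
})
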