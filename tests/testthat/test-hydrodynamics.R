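test_that("reactor geometry follows from volume and aspect ratio", {
  g <- reactor_geometry(600, 6, 0.95)
  expect_equal(g$D_R, (4 * 600 / (6 * pi))^(1 / 3), tolerance = 1e-12)
  expect_equal(g$H_R, 6 * g$D_R)
  expect_equal(g$H_aerated, 0.95 * g$H_R)
  expect_error(reactor_geometry(fill_fraction = 1.2),
               class = "scp_invalid_config")
})

test_that("kLa correlation reproduces the regime-window endpoints", {
  expect_equal(kla(0.30, 30), 617, tolerance = 0.002)
  expect_equal(kla(0.04, 30), 150, tolerance = 0.005)
  # at the correlation reference temperature the factor is exactly one
  v <- 0.17
  expect_equal(kla(v, 20), 0.32 * v^0.7 * 3600, tolerance = 1e-12)
  expect_error(kla(-0.1, 30), class = "scp_domain_error")
  expect_warning(kla(0.5, 30), class = "scp_correlation_range")
})

test_that("kLa grows sublinearly and the CO2 correction is a constant ratio", {
  vs <- seq(0.04, 0.30, length.out = 10)
  k <- vapply(vs, function(v) kla(v, 30), numeric(1))
  expect_true(all(diff(k) > 0))
  # sublinear: kLa per unit velocity falls
  expect_true(all(diff(k / vs) < 0))
  props <- physical_properties()
  want <- sqrt(props$diffusivity[["CO2"]] / props$diffusivity[["O2"]])
  for (v in c(0.05, 0.15, 0.30))
    expect_equal(kla(v, 30, "CO2") / kla(v, 30, "O2"), want,
                 tolerance = 1e-12)
})

test_that("gas hold-up correlation matches the window endpoints", {
  expect_equal(gas_holdup(0.30), 0.26, tolerance = 0.01)
  expect_equal(gas_holdup(0.04), 0.06, tolerance = 0.06)
  expect_equal(gas_holdup(0), 0)
  vs <- seq(0.01, 0.5, length.out = 20)
  expect_true(all(diff(vapply(vs, gas_holdup, numeric(1))) > 0))
})

test_that("superficial velocity and molar flow are exact inverses", {
  g <- reactor_geometry()
  for (v in c(0.01, 0.1, 0.45)) {
    F <- molar_gas_flow(v, 1.7, 303.15, g)
    expect_equal(superficial_velocity(F, 1.7, 303.15, g), v,
                 tolerance = 1e-14)
  }
  # single-line arithmetic oracle at 1 mol/s
  v <- superficial_velocity(3600, 1, 303.15, g)
  expect_equal(v, (8.314462618 * 303.15 / 1e5) / (pi / 4 * g$D_R^2),
               tolerance = 1e-12)
  # doubling pressure halves the velocity
  expect_equal(superficial_velocity(3600, 2, 303.15, g), v / 2,
               tolerance = 1e-12)
  expect_error(superficial_velocity(10, -1, 303.15, g),
               class = "scp_domain_error")
})

test_that("log mean lies between its arguments and has the right limit", {
  expect_equal(log_mean(0.3, 0.1), 0.2 / log(3), tolerance = 1e-14)
  expect_equal(log_mean(0.2, 0.2), 0.2)
  for (p in list(c(1, 4), c(0.04, 0.3), c(7, 2))) {
    lm <- log_mean(p[1], p[2])
    expect_gt(lm, min(p)); expect_lt(lm, max(p))
  }
  expect_error(log_mean(-1, 2), class = "scp_domain_error")
})

test_that("bottom pressure adds the aerated hydrostatic head", {
  g <- reactor_geometry()
  # arithmetic oracle at the base-case hold-up
  expect_equal(bottom_pressure(1.2, 0.26, g),
               1.2 + 1000 * 0.74 * 9.80665 * g$H_aerated / 1e5,
               tolerance = 1e-12)
  expect_gte(bottom_pressure(1.2, 0.999, g), 1.2)
  eps <- seq(0, 0.9, by = 0.1)
  pb <- vapply(eps, function(e) bottom_pressure(1.2, e, g), numeric(1))
  expect_true(all(diff(pb) < 0))
  expect_true(all(pb >= 1.2))
})

test_that("transfer rate vanishes at equilibrium and follows the driving force", {
  props <- physical_properties()
  KH <- henry_coefficient("O2", 303.15, props)
  Ceq <- KH * 0.8 * 2.0
  expect_equal(transfer_rate("O2", 0.8, 2.0, Ceq, 600, 303.15, props), 0,
               tolerance = 1e-15)
  # algebraic identity N = kla * driving force
  N <- transfer_rate("O2", 0.8, 2.0, 6.9e-5, 617, 303.15, props)
  expect_equal(N / 617, KH * 0.8 * 2.0 - 6.9e-5, tolerance = 1e-12)
  # negative transfer (liquid to gas) is legal
  expect_lt(transfer_rate("CO2", 0.01, 1.2, 0.02, 500, 303.15, props), 0)
})

test_that("evaporation is linear in the gas outflow and capped by saturation", {
  ev1 <- evaporation_rate(1e6, 1.2, 303.15, 4e5)
  ev2 <- evaporation_rate(2e6, 1.2, 303.15, 4e5)
  expect_equal(ev2$N_W, 2 * ev1$N_W, tolerance = 1e-12)
  expect_equal(ev1$y_W, water_vapor_pressure(303.15) / 1.2, tolerance = 1e-14)
  expect_lt(ev1$N_W, 0)
  expect_error(evaporation_rate(1e6, 0.03, 303.15, 4e5),
               class = "scp_saturation_error")
})
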