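test_that("degree of reduction follows 4C + H - 2O - 3N", {
  expect_equal(degree_of_reduction("C2H6O"), 12)       # ethanol
  expect_equal(degree_of_reduction("C6H12O6"), 24)     # glucose
  expect_equal(degree_of_reduction("CH1.8O0.5N0.2"), 4.2)
  expect_equal(degree_of_reduction("CH4"), 8)
  expect_error(molecular_formula(0, 0, 0, 0), class = "scp_invalid_formula")
  expect_error(parse_chemical_formula("XeF4"), class = "scp_invalid_formula")
})

test_that("formula parsing handles decimal counts and molar mass", {
  f <- parse_chemical_formula("CH1.8O0.5N0.2")
  expect_equal(f$molar_mass, 24.6, tolerance = 2e-3)
  expect_equal(parse_chemical_formula("C2H6O")$molar_mass, 46.07,
               tolerance = 1e-3)
})

test_that("Herbert-Pirt uptake and Monod inversion reproduce the base case", {
  up <- substrate_uptake(0.15, kinetic_parameters())
  expect_equal(-up$qS / 0.15, 0.88, tolerance = 0.005)  # mol_S/mol_x
  expect_equal(up$residual_CS * 1000, 1.1, tolerance = 0.05) # mmol/kg
  # derived qS_max from mu_max
  expect_equal(up$qS_max, 0.191, tolerance = 0.005)
  # maintenance-only limit at zero growth
  expect_equal(substrate_uptake(0)$qS, -0.005)
})

test_that("washout is reported at and beyond mu_max", {
  expect_error(substrate_uptake(0.22), class = "scp_washout")
  expect_error(substrate_uptake(0.30), class = "scp_washout")
  expect_error(process_reaction(0.25), class = "scp_washout")
})

test_that("process reaction at mu = 0.15 matches the reference coefficients", {
  st <- process_reaction(0.15)
  nu <- st$coefficients
  expect_equal(unname(nu[["biomass"]]), 1)
  # agreement to one unit in the last printed digit (the reference table's
  # O2 and H2O entries were derived from the rounded substrate coefficient)
  ref <- c(substrate = -0.88, O2 = -1.59, CO2 = 0.76, H2O = 2.04,
           NH3 = -0.20)
  expect_true(all(abs(nu[names(ref)] - ref) <= 0.01))
  expect_equal(st$RQ, 0.48, tolerance = 0.01)
  expect_equal(st$Y_xs, 0.61, tolerance = 0.01)
})

test_that("element and electron balances close for any growth rate", {
  gamma <- function(f) 4 * f$C + f$H - 2 * f$O - 3 * f$N
  for (mu in c(0.01, 0.05, 0.10, 0.15, 0.20, 0.219)) {
    st <- process_reaction(mu)
    nu <- st$coefficients
    x <- st$biomass; s <- st$substrate
    species <- list(x, s, molecular_formula(O = 2), molecular_formula(C = 1, O = 2),
                    molecular_formula(H = 2, O = 1), molecular_formula(H = 3, N = 1))
    for (el in c("C", "H", "O", "N")) {
      bal <- sum(nu * vapply(species, `[[`, numeric(1), el))
      scale <- max(abs(nu * vapply(species, `[[`, numeric(1), el)))
      if (scale > 0) expect_lt(abs(bal) / scale, 1e-10)
    }
    ebal <- gamma(x) * 1 + gamma(s) * nu[["substrate"]] - 4 * nu[["O2"]]
    expect_lt(abs(ebal) / (4 * abs(nu[["O2"]])), 1e-10)
    expect_lt(st$closure_residual, 1e-10)
  }
})

test_that("glucose stoichiometry agrees with a sequential-balance oracle", {
  glc <- parse_chemical_formula("C6H12O6")
  st <- process_reaction(0.15, kinetic_parameters(Y_xs_max = 0.5),
                         substrate = glc)
  nu <- st$coefficients
  nuS <- nu[["substrate"]]
  # closed-form sequential balances, independent of the linear solve
  expect_equal(nu[["CO2"]], -(1 + 6 * nuS), tolerance = 1e-12)
  expect_equal(nu[["NH3"]], -0.2, tolerance = 1e-12)
  expect_equal(nu[["O2"]], (4.2 + 24 * nuS) / 4, tolerance = 1e-12)
  expect_equal(nu[["H2O"]], -(1.8 + 12 * nuS + 3 * nu[["NH3"]]) / 2,
               tolerance = 1e-12)
  expect_lt(st$closure_residual, 1e-10)
})

test_that("yield rises with growth rate toward the maximum", {
  mus <- seq(0.01, 0.21, by = 0.02)
  Y <- vapply(mus, function(m) process_reaction(m)$Y_xs, numeric(1))
  expect_true(all(diff(Y) > 0))
  expect_lt(max(Y), 0.63)
  expect_gt(Y[length(Y)], 0.60)
  # without maintenance the realized yield equals the maximum everywhere
  no_maint <- kinetic_parameters(m_S = 0)
  Y0 <- vapply(mus, function(m) process_reaction(m, no_maint)$Y_xs, numeric(1))
  expect_equal(Y0, rep(0.63, length(mus)), tolerance = 1e-12)
})

test_that("residual substrate rises with growth rate and diverges near washout", {
  mus <- seq(0.01, 0.219, length.out = 20)
  CS <- vapply(mus, function(m) substrate_uptake(m)$residual_CS, numeric(1))
  expect_true(all(diff(CS) > 0))
  expect_gt(CS[20] / CS[1], 50)
})
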