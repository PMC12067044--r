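Package: scpreactor
Title: Steady-State Bubble-Column Bioreactor Model for Single-Cell-Protein
    Production
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic steady-state model of an industrial bubble-column
    bioreactor producing single cell protein (dry microbial biomass) by
    aerobic growth on ethanol or other CHON substrates, sparged with pure
    oxygen or air.  Provides growth-rate-dependent process-reaction
    stoichiometry from Herbert-Pirt kinetics with elemental and
    degree-of-reduction balances, coalescing-broth kLa and gas hold-up
    correlations, a staged gas/liquid material-balance solver, a heat
    balance with external cooling-loop sizing and cell-stress diagnostics,
    characteristic-time regime analysis for scale-up gradient screening,
    and named sensitivity scenarios.  All physical constants are exposed
    through a structured configuration whose defaults describe a 600 m3
    column operated as a chemostat at a dilution rate of 0.15 per hour.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
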