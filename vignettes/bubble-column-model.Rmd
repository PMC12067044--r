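---
title: "A steady-state bubble-column model for single-cell-protein production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state bubble-column model for single-cell-protein production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpreactor)
```

## The process and the modelling question

Single cell protein (SCP) — dry microbial biomass grown as a protein
source — can be produced aerobically from ethanol in a large bubble
column run as a chemostat.  At industrial scale the achievable
productivity is set almost entirely by how fast O2 can be moved from the
gas into the broth, and the design couples several mechanisms that are
usually treated separately: microbial stoichiometry, bubble-column
hydrodynamics, gas-liquid transfer, the plant heat balance, and mixing.
`scpreactor` implements that coupled steady-state model for a 600 m3
column (height-over-diameter 6, so 5.03 m wide) sparged with pure O2 or
air, and answers, for any operating point in the heterogeneous flow
regime: what biomass concentration, production rate, feed flows, cooling
plant, and gradient risks follow?

All model constants live in a single nested configuration
(`scp_config()`), so every correlation coefficient, solubility and
catalogue number can be overridden without touching code.

## Growth stoichiometry

Dry biomass is described by the standard unit-carbon formula
CH1.8O0.5N0.2 (24.6 g/mol).  At a dilution rate $D$ the chemostat fixes
the specific growth rate $\mu = D$, and the Herbert–Pirt relation
partitions substrate uptake into growth and maintenance,

$$ -q_S = \frac{\mu}{Y^{max}_{x/S}} + m_S , $$

with $Y^{max}_{x/S} = 0.63$ g/g (converted to molar units with the exact
molar masses), $m_S = 0.005$ mol$_S$/(mol$_x$ h) and
$\mu_{max} = 0.22$ 1/h.  The maximum uptake rate is derived from the same
relation evaluated at $\mu_{max}$ (0.191 mol$_S$/(mol$_x$ h)), and
inverting the Monod hyperbola with $K_S = 5\times10^{-4}$ mol/kg gives
the residual ethanol concentration.  The remaining reaction coefficients
(O2, CO2, H2O, NH3 per mole of biomass) follow from the carbon, hydrogen,
nitrogen and electron (degree-of-reduction, $\gamma = 4C + H - 2O - 3N$)
balances, solved as a small linear system; the redundant oxygen balance
is kept as a closure check and must vanish to $10^{-10}$ relative.

```{r}
process_reaction(0.15)
```

Coefficients are carried at full precision; note that a reference table
rounded to two decimals, if built from an already-rounded substrate
coefficient, can differ from the full-precision values by up to 0.006 in
the O2 and H2O entries.

## Hydrodynamics and transfer

For a coalescing broth in the heterogeneous regime (mean superficial gas
velocity $v_{sG}$ between 0.04 and 0.30 m/s) the model uses the classical
correlations $k_La_{O2} = 0.32\,v_{sG}^{0.7}\,1.022^{T-20}$ (1/s) and
$\varepsilon_G = 0.6\,v_{sG}^{0.7}$.  Outside the validity window the
functions warn but do not refuse, since sensitivity studies legitimately
probe the edges.  The CO2 coefficient is the O2 value times
$\sqrt{D_{CO2}/D_{O2}}$; only that ratio matters, and it is overridable.

The transfer driving force uses the ideally-mixed off-gas composition at
an effective column pressure.  Since the averaging behind the "log-mean
equilibrium concentration" is a genuinely open choice, the package
implements three variants (`correlations$pressure_mean`): the log-mean of
top and bottom total pressure (default), the arithmetic mean, and the top
pressure.  The default reproduces the published transfer rates within the
solubility uncertainty discussed below.

Henry coefficients are Sander-type compilation values at 298.15 K with
van't Hoff temperature dependence.  The O2 value, 1.2e-3 mol/(kg bar)
with 1500 K, was chosen because it is simultaneously a standard
compilation value and consistent with the operating rule that a dissolved
O2 setpoint of 0.069 mmol/kg is 30% of air saturation at 30 C; the CO2
value (3.3e-2, 2400 K) makes CO2 about 25 times more soluble than O2.
Water vapor pressure uses an Antoine correlation whose constants sit in
the configuration.  Salinity corrections, electrolyte models and CO2
speciation are out of scope: at pH 6 dissolved CO2 is treated as
molecular CO2 only.

## The staged steady-state solver

Given the stoichiometry, the gas phase is closed by a single scalar
root-find.  For a candidate top velocity, the bottom velocity is varied
until the O2 transfer rate implied by the gas-phase material balances
(total balance with $N_{CO2} = -RQ \cdot N_{O2}$ and the equilibrium
evaporation flux) equals the rate given by the $k_La$ law at the implied
off-gas composition.  Gas hold-up, liquid mass and bottom pressure are
recomputed inside every residual evaluation, so the
hold-up/hydrostatic-pressure coupling is fully nested.  The root is
bracketed by scanning a geometric grid and polished to a relative
residual below $10^{-9}$; there are no stochastic elements anywhere, so
results are bit-reproducible.  Because users reason in terms of the
column-mean velocity while the natural iteration variable is the top
velocity, both specifications are supported; a mean target adds an outer
bracketed root-find.

The liquid side then follows explicitly: liquid mass from the hold-up,
production rates from the stoichiometry, outflow from the dilution rate,
the ammonia feed sized for a 1 g/kg residual at a 200 g/kg feed strength,
and the ethanol feed closing the total mass balance (including the net
gas-to-liquid mass flux, about 5 t/h at the base point — the plant gains
mass from the gas phase).  All ten steady-state balances close on the
stored solution to $10^{-9}$ relative; an independent simultaneous
Newton solve of the whole system is kept in the test suite as a
cross-check.

One deliberate approximation mirrors the staged procedure: the dissolved
CO2 leaving with the liquid outflow is neglected on the gas side.
`carbon_balance_error()` quantifies the consequence as the extra carbon
leaving as dissolved CO2 relative to the carbon fed (about 1% at
0.04 m/s, 0.1% at 0.30 m/s — the denominator of this error is a
documented package choice, as no unambiguous definition reproduces all
published figures).  The dissolved O2 outflow is likewise neglected (a
$10^{-5}$ relative effect), keeping the O2 liquid balance in its
published form.

```{r}
sol <- solve_operating_point(scp_config(), vsG_mean = 0.30)
sol
```

## Heat balance and cooling loop

Heat generation is tied to O2 consumption at 460 kJ/mol; evaporation
withdraws `FG_out * y_W * 43.5` kJ/mol of latent heat (a <5% correction),
and the rest must be removed by cooling.  With an overall coefficient of
1.4 kW/(m2 K) and a 15 K log-mean temperature difference, the base case
needs about 2830 m2 of area — far beyond the ~474 m2 an internal helical
coil could provide (pipe diameter $D_R/30$, pitch twice that, turns
filling the aerated height), hence the external loop.  The exchanger
count is taken as the ceiling of the required area over the largest
catalogue shell-and-tube unit (430 m2), and the per-unit area is
reported; at the base case this gives seven units of ~404 m2, matching
the published seven-of-400 m2 design.  (Dividing by the 400 m2 design
area instead would give eight units for any area above 2800 m2, which
contradicts the published count at the published area — the catalogue
rule is the design decision here.)

The stress profile compares the loop residence time against the times in
which cells deplete dissolved O2 and substrate at the bulk rates.  Tube
velocity uses the catalogue tube count scaled to the design area
(1269 x 400/430 per unit, the default; the unscaled count is available
and gives ~10% lower velocity — the tube count behind the published
0.41 m/s is not stated, so this target carries a wider ±15% tolerance).
Wall shear uses the simple estimator $\mu v/d$, which is what the
published shear figures imply, with the rigorous laminar $8\mu v/d$
reported alongside; the pump shear is the blade-tip speed over the
0.3 mm tip clearance.  Broth viscosity is taken as 10 mPa s.

```{r}
d <- size_cooling_system(sol)
d
stress_profile(d, sol)
```

O2 depletion (~0.2 s at the base point) is always faster than the loop
residence (~40 s), so cells are anoxic for most of every cooling pass —
a scale-down finding the model surfaces as an inequality test.

## Characteristic times and gradient screening

Times are reservoir-over-rate constants: dissolved reservoirs over
volumetric conversion rates for substrate, O2 and CO2; heat capacity
times a 1 K allowed excursion over the specific heat load; liquid volume
over the gas-driven circulation flow
$F_{mix} = 0.3 D_R^{5/3} (F^V_G)^{1/3} g^{1/3}$ for liquid mixing; the
gas hold-up volume over the same circulation flow for gas mixing; and
the hold-up volume over the mean volumetric gas throughput for gas
flow-through.  The last two formulas are package choices (the original
definitions are not published): they reproduce the reported ~1/4 ratio
of gas mixing to gas flow-through at the base point, but with these
definitions the gas mixing time *rises* with gas velocity (hold-up grows
like $v^{0.7}$, circulation like $v^{1/3}$), so the claim that every time
constant falls with velocity cannot hold simultaneously — the
monotonicity is asserted for all other times only.

Gradients are only flagged when mixing is outrun by more than an order
of magnitude (`gradient_flags()`, threshold 10 by default).  At the base
point liquid mixing (~25 s) is ~110 times slower than O2 consumption and
~4 times slower than substrate consumption; with a tenfold lower $K_S$
the substrate time drops tenfold and the substrate flag trips — the
quantitative argument for multiple feed points.
`transfer_capacity_ratio()` brackets the bottom/top O2 transfer ratio
between the well-mixed (~3) and plug-flow bounds, rising to ~4/~56 if
the off-gas O2 fraction were driven down to 0.1.

```{r}
ct <- characteristic_times(sol)
gradient_flags(ct)
```

## Scenarios

`run_scenario()` solves a named override set against an untouched
baseline over a velocity grid.  Built-ins: `yield10` (+10% maximum
yield: −8.7% substrate and −14.5% O2 per mole of biomass, so +18–20%
productivity), `ks10`, `hot45` (kLa +39%, O2 solubility −21% with the
adopted van't Hoff constant, a small net transfer gain), `coalescence3`
(kLa tripled; utilization and titer gains grow along the velocity grid
and span the published mid-window figures), and `air` (nitrogen balance
active; pure O2 outproduces air more than threefold at equal velocity).
Because the published coalescence gains are single numbers while the
model's deltas vary along the grid, the tests assert that the published
figures lie within the sweep's range rather than at one point.

## Numerical choices, degenerate inputs, limitations

* Root-finds are bracketed bisection/Brent (`uniroot`) at $10^{-12}$
  step tolerance with an explicit residual check at $10^{-9}$ relative;
  infeasible off-gas compositions (negative mole fractions) and
  unreachable dissolved-O2 setpoints raise classed errors rather than
  returning unconverged numbers.
* Washout ($D \ge \mu_{max}$, or required uptake above $q_S^{max}$) is a
  classed error; the dilution-rate study marks such grid points instead
  of failing.
* Zero cooling duty collapses the exchanger design to zero units;
  requesting a stress profile on it errors.
* The problem sizes throughout (14-point sweeps, 4-point scenario grids)
  solve in well under a second each; the full test suite runs in seconds.
* Not modelled: time-course dynamics, spatial compartments or CFD, CO2
  growth inhibition (the model reports the concentration against the
  13 mmol/kg sensitivity landmark instead), broth rheology above
  150 g/kg biomass (the model reports proximity to that ceiling),
  ethanol/NH3 evaporation, foam, economics.
* The configuration file format is YAML (no TOML reader is required by
  the package's dependencies); an empty file means "all defaults".
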