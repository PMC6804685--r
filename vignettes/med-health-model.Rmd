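---
title: "An integrated tariff–diet–cardiovascular-health simulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated tariff–diet–cardiovascular-health simulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the model structure and its assumptions, the parameters
that matter and their defaults, what the synthetic data generator does
and does not emulate, the numerical choices, and the known limits.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The question the framework answers

Import tariffs on food change consumer prices, consumer prices change
diets, diets change the composition of fatty-acid energy intake, and
fatty-acid composition drives the Total:HDL serum cholesterol ratio — a
validated biomarker for cardiovascular disease (CVD) risk. A tariff is
therefore simultaneously a fiscal instrument, a dietary instrument, and
(through land reallocation between crops) an environmental instrument.
The framework quantifies all three channels in a single consistent
model, so that the cost per person-year saved of a protective food
tariff can be compared with conventional cost-effectiveness thresholds.

## 2. Economic core

### 2.1 Calibration

`cge_calibrate()` reads a balanced social accounting matrix (SAM) with
activities, commodities, seven production factors (unskilled and
skilled labour, capital, four regional land types), nine regional
household types, government, a savings–investment account, and the rest
of the world. Share and shift parameters of every nest are chosen so
that solving the model at base policy reproduces the SAM exactly
("benchmark replication", asserted at 1e-8 in the tests).

Nesting and elasticities (defaults; all overridable):

| Nest | Form | σ |
|---|---|---|
| output = f(value added, intermediates) | CES | 0.8 |
| value added = f(7 factors) | CES | 0.6 |
| intermediates | Leontief | — |
| import/domestic composite | Armington CES | 0.8 |
| export/domestic split | CET | 1.6 |

The land first-order condition of the value-added nest is the familiar
`FLAND = (δ αVA^ρ)^{1/(1+ρ)} (PVA/WFLAND)^{1/(1+ρ)} QVA`; land is
mobile across crops within a region, fixed in total per region.

### 2.2 Demand

Household expenditure shares are Almost Ideal:
`w_c = α_c + β_c log(e/P) + Σ_{c'} γ_{cc'} log p_{c'}`,
`x_c = w_c e / p_c`. Two deliberate variants relative to the textbook
system:

* the deflator `P` is the model's GDP deflator (solved as an explicit
  unknown of the within-period system), not the translog price index —
  this is the form the source framework writes down;
* consequently the calibration map from literature elasticities is
  `β_c = w_c(η_c − 1)` and `γ_{cc'} = w_c(ε_{cc'} + δ_{cc'})`,
  evaluated at the base point.

Literature elasticities are generically inconsistent with exact
adding-up/homogeneity/symmetry, so `aids_calibrate()` projects the
target parameters onto the constraint set by least squares
(parameterising γ by its upper triangle and solving the KKT system
directly); the projection distance is recorded in the `projection`
attribute. AIDS is not globally regular: predicted shares can go
negative far from the base point. Shares below zero are clipped and
renormalised; violations beyond −0.01 raise a warning. Over the
20-year growth path the smallest expenditure shares (edible oils, below
0.2% of budgets) do hit this guard in late years — the warnings seen
during `calibrate_trends()` are this mechanism, not an error.

### 2.3 Closure, numéraire, dynamics

Prices clear all markets; a flexible real exchange rate clears the
fixed current account; savings drive investment. The consumer price
index is the numéraire and follows an exogenous price-trend factor.
Counterfactual (business-as-usual) runs use a balanced fiscal rule —
nominal government consumption is a fixed share of absorption — while
every scenario simulation (including the free-trade baseline) holds
real government consumption to the counterfactual path.

One commodity-clearing equation is dropped from the square Newton
system and verified afterwards as the Walras residual (asserted ≤ 1e-8
in every solved year). The solver is a damped Newton iteration on the
logs of all positive unknowns with a forward-difference Jacobian and a
halving line search; on failure it restarts along a homotopy path in
the tariff vector. Warm starts (the previous year's or the reference
run's solution) keep within-loop solves at a handful of iterations.

Recursive dynamics: capital follows
`K_{t+1} = (1 − δ)K_t + real investment` with δ = 0.05 (the source
framework names but does not print its updating equations; δ = 0.05 is
the conventional choice); labour follows the demographic module; land
is fixed. `dynamic_calibrate()` finds, year by year, the Hicks-neutral
productivity factor putting counterfactual real GDP on a 3.9% p.a.
path (secant iteration, tolerance 1e-8 on the yearly ratio), and sets
the price-trend factor so nominal GDP grows at 6.2% p.a. — exact by
degree-one homogeneity in the numéraire, which the tests verify
directly.

## 3. Health chain

**Nutrition.** Fatty-acid energy intake shares are consumption-weighted
ratios `e^F = Σ_c α^F_c x_c / Σ_c α^Tot_c x_c` for F ∈ {SFA, MUFA,
PUFA}. Cholesterol build-up is
`Δchol = c_SFA Δe_SFA + c_MUFA (e_MUFA/e_Tot) Δe_MUFA + c_PUFA Δe_PUFA`
with defaults (+0.3, −2.6, −3.2 per unit share — i.e. +0.003, −0.026,
−0.032 per percent of energy), the magnitudes of the controlled-trial
literature on fatty-acid substitution and the Total:HDL ratio. The
`e_Tot` in the MUFA weight is implemented as the total fatty-acid share
(the symbol is undefined in the source); `mufa_term = "linear"`
switches the term to plain linear. Year-on-year share changes drive
the dynamic loop.

**Biomarker distributions.** Each household carries a mean Total:HDL
ratio and a 10-stratum frequency distribution over [2.0, 7.0]
(equidistant bins; representative value = bin midpoint, the symmetric
choice). Policy shifts move every representative value by the mean
change, clamped to the admissible range; frequencies — hence
probability mass — never change.

**Clinical outcomes.** Rates for non-fatal/fatal MI and stroke are
degree-10 polynomials in the biomarker per gender × age × location
cell, Horner-evaluated at the stratum values and mixed by the
frequencies into incident levels `Σ_s freq_s rate_s POP`. The
published lookup tables are survey-calibrated and unavailable, so
`generate_lookup()` builds a synthetic stand-in: a logistic hazard
curve (baseline rates rising exponentially with age, male > female,
urban > rural; log relative risk 0.45 per biomarker unit for MI, 0.25
for stroke) fitted on 200 Chebyshev nodes in a conditioned variable and
expanded to raw monomial coefficients. The fit is verified on a
1,001-point grid: error ≤ 1e-6, range within [0, 1], monotone
non-decreasing to 1e-9.

**Demography.** Annual cohort-component recursion over 15 five-year
age groups: survive, stay (net of emigration), then transition to the
next group with probability `p_trans` (≈ 0.2 in steady state — the
device that reconciles five-year groups with an annual step); births
apply a sex ratio to fertility-weighted previous-year female
populations; the 70+ group accumulates. `calibrate_transitions()`
solves the probabilities sequentially in age against a target
population path — exactly feasible for the fixture, whose baseline path
is itself a forward run with planted probabilities (recovered to 1e-8
in the tests); the terminal group supplies a feasibility residual.
Policy mortality adds the policy-minus-counterfactual difference in
fatal-illness excess rates to counterfactual all-cause mortality,
assuming no double counting.

**Feedbacks.** Caregiver work/leisure time losses and YLD morbidity
are rate × illness duration × summed non-fatal incident levels
(duration 28/365 years for non-fatal MI, 1 year for non-fatal stroke;
YLD weights 0.12 and 0.27). Patient worktime losses are
participation-weighted YLD, indexed over the non-fatal illnesses for
consistency with the YLD definition (`patient_over_fatal = TRUE`
recovers the literal indexing). Effective labour supply is the
skill-share split of the participation-weighted 15–64 population net of
the loss deltas. Formal health costs scale with the GDP deflator and
accumulate over lags 0–3 (lags 1–3 non-zero only for stroke), split
80/20 public/private; public costs are government health purchases,
private costs reduce disposable income. Within the annual loop both
feedbacks enter the economy with a one-year lag, the standard
recursive-dynamic device for breaking within-period simultaneity — the
standalone operations implement the accounting without the lag.

## 4. Land use and emissions

Within each region, the crop-level land reallocation between
consecutive years is pooled (total positive change), split into gain
and loss shares (zero-change crops fall into the loss set with zero
magnitude), and assigned to bilateral loser→gainer flows
proportionally. Emission coefficients are differences of per-crop
carbon-stock scalars (rubber 120 > oil palm 100 > fruit/vegetables 60 >
sugarcane 30 > cassava 20 > maize 18 > rice 15 t CO2-eq/ha, scaled to
Mt), antisymmetric by construction. A run's emission indicator is the
cumulative sum of yearly changes; the scenario indicator is the
policy-minus-counterfactual difference in the final year.

## 5. The synthetic world

`make_fixtures(seed = 20160101)` is a pure function of its seed and the
share-target table. It reproduces exactly the published sectoral
structure (import share of sales, export share of production, tariff
rate, sales share, household share for eight sectors; the printed
columns sum to 100.1%, so the two largest shares are trimmed by at most
0.05pp each to restore adding-up). Everything the publication does not
pin down is invented once, documented, and frozen:

* 49 fine sectors (six food crops and rubber are real model sectors;
  the rest are Dirichlet splits of their aggregates), balanced by RAS;
* the model runs at a 14-sector resolution — crops stay disaggregated
  for the land module; demand, nutrition and trade run at this level;
* nine regional households with seeded factor-income, taste and
  savings heterogeneity; income tax 10%;
* plausible nutrient densities per commodity (palm oil SFA-heavy,
  other edible oils PUFA-heavy, non-foods zero);
* a 64-million-person population with a middle-income age pyramid,
  total fertility ≈ 1.5, Gompertz-like mortality declining 0.5%/year.

Two properties of this world deserve flagging. First, the published
share structure forces exports to exceed imports by a wide margin; the
fixture finances the surplus through repatriation of 85% of capital
income and a high household saving rate. This is internally consistent
but makes the economy more savings- and trade-intensive than any real
middle-income country. Second, all policy magnitudes (person-years,
USD impacts, Mt CO2-eq) are properties of this synthetic economy.
A green test therefore establishes that the *machinery* — calibration,
equilibrium, transmission, accounting — is correct at stated
tolerances; it does not reproduce, and cannot reproduce, the
publication's headline Thailand numbers, which depend on confidential
survey calibration.

## 6. Numerical choices

* Newton tolerance 1e-11 on scaled residuals (market clearing scaled
  by base quantities, monetary identities by base GDP); benchmark
  replication and Walras checks at 1e-8.
* RAS balancing: tolerance 1e-9, cap 10,000 iterations, zero cells
  preserved; infeasible margins (zero row with positive target) raise
  an error rather than cycling.
* Degenerate accounts (no trade, no government, no investment) drop
  their unknowns and equations, so closed two-sector test economies
  solve without dummy flows; σ = 1 nests use the Cobb–Douglas limit.
* Ties and clamps: biomarker values clamp to [2.0, 7.0]; transition
  probabilities and mortality clamp to [0, 1] with warnings and
  counters; AIDS shares clip at 0 with renormalisation.
* Determinism: every stochastic draw flows from one seeded generator
  inside `with_seed()`, which restores the caller's RNG state; two
  same-seed bundles and two same-spec scenario runs are bit-identical.

## 7. Known limitations

* Energy-intake *levels* (obesity pathways) are out of scope; only
  fatty-acid composition drives risk.
* The clinical lookup generator is a logistic stand-in, not the
  published relative-hazard estimation; its parameters are documented
  defaults, not estimates.
* Cumulative monetary indicators are undiscounted sums, matching the
  publication's presentation, and "long-run" means the final simulated
  year.
* The cost-per-person-year rounding rule (nearest 100k at or above
  500k, else nearest 10k) reproduces two of the three published
  figures; the third (≈ 670k) is the unrounded quotient at its printed
  granularity, which the acceptance test checks directly.
* Non-tariff barriers, multi-country trade, and sugar-sweetened
  beverage disaggregation are out of scope by design.
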