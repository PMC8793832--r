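---
title: "Methods: from commodity balance sheets to nutrient adequacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from commodity balance sheets to nutrient adequacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriflow)
```

## The model

`nutriflow` is an accounting model, not a statistical one: given a
description of what the food system produces, it computes deterministically
how much of each of 29 essential nutrients is available per person per day,
and how that compares with what the population requires. The calculation
chain is

1. **Baseline.** Each commodity's production, food supply and supply-chain
   losses are annual series; the baseline at a target year is the ordinary
   least-squares linear trend over the most recent 20 observations,
   evaluated at the target year. A trend over the full window is the only
   estimator that uses all 20 years; carrying the last observation forward
   is available as `baseline_method = "last_value"` for sensitivity
   checks. We fit the trend to each balance quantity directly (rather than
   fitting components and recombining) because the quantities are reported,
   not derived, in balance-sheet data.
2. **Subdivision and waste.** Commodities split into food types by share
   (shares under a commodity must sum to 1), each with a processing yield
   (mass out per mass in; may exceed 1 for hydrating processes) and an
   inedible fraction. In-home waste is a fraction per region × food group;
   we apply the region-population-weighted mean fraction to global supply.
   At global scale, for a fixed food group, this is algebraically identical
   to applying regional fractions before aggregating, so nothing is lost by
   working with the weighted mean.
3. **Nutrients.** Composition is stored per 100 g edible mass in canonical
   units (g for macronutrients and amino acids, kcal for energy, mg for
   most minerals and vitamins, µg for folate, vitamin A, B12 and selenium).
   All unit conversion happens at the input boundary; internal computation
   is unit-free. Bioavailability coefficients in [0, 1] multiply protein
   and the seven indispensable amino acids only; for every other nutrient
   the coefficient is identically 1, reflecting the absence of reliable
   absorption data for minerals and vitamins across foods.
4. **Targets.** The global daily requirement for a nutrient is the
   population-weighted sum of per-group reference values; the per-capita
   target is that requirement divided by total population. Plain division
   is used — no age group is excluded — because no principled exclusion
   rule is available at this level of aggregation. A single reference value
   per group × nutrient is carried; whether it encodes an average
   requirement or a recommended intake is a property of the input table,
   not of the code.
5. **Analytics.** Contribution percentages and ranks are computed at the
   commodity level (food types aggregate to their parent) using the
   bioavailability-adjusted quantities — for the 21 unadjusted nutrients the
   two bases coincide. Nutrient density is the edible-mass-weighted mean of
   a commodity's food-type contents per 100 g, using mass after
   inedible-fraction removal but before in-home waste: "content per 100 g"
   describes food as available, not as eaten. A per-food-type
   representative alternative (`method = "representative"`) is provided
   because the weighted-mean choice, while natural, is not the only
   defensible one.
6. **Scenarios.** A scenario assigns each of the 15 primary food groups a
   production multiplier (or an absolute value, converted to a multiplier
   against the baseline group production). All commodities within a group
   scale uniformly; scenarios never alter composition, coefficients,
   reference values or demographics. A supply-chain-loss override resets
   losses to the given fraction of production and moves the difference into
   food supply (clamped at zero), so that reducing losses increases what
   reaches consumers; an in-home waste override replaces the weighted mean
   fraction globally. The gap-closing solver uses the closed form
   k = (T − S_others) / S_group, which is exact because the pipeline is
   linear in any one group's supply, and every solution is verified by
   re-running the adequacy computation at k.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `window` | 20 | years | smooths year-to-year reporting noise while tracking secular trends |
| `target_year` | last data year | year | the system the data most recently describes |
| `baseline_method` | `"trend"` | — | uses all observations in the window |
| `waste_override` | none | fraction | scenario-level replacement of in-home waste |
| `density_method` | `"weighted"` | — | commodity density as consumption-weighted mean |
| DIAAS `reference_pattern` | input | mg/g protein | the recommended pattern differs by age group, so it is data, not a constant |

## The synthetic-data generator

Real inputs (balance sheets, composition tables, demographic counts,
reference values) require downloads, so the generator emits all seven input
tables of an internally consistent system. Its defaults emulate the scale
of the real data: 98 commodities, one to six food types each (≈ 315 in
expectation), 20-year series ending in 2018, and a milk-like dairy
commodity whose bioavailability coefficients are exactly the canonical
eight values (protein 0.95, tryptophan 0.98, threonine 0.97, leucine 1,
lysine 0.98, methionine 0.92, cystine 0.94, histidine 1), whose fiber
content is exactly zero, and whose regional in-home waste fractions lie in
[0.001, 0.15]. Time series are linear trends with multiplicative Gaussian
noise (relative s.d. 0.02 by default, slopes between −2% and +5% of the
base level per year), truncated at zero because masses are non-negative.
Demographics use four age bands × two sexes; reference values are uniform
draws around realistic per-nutrient midpoints — placeholders with correct
magnitudes, not agency values.

Every generated bundle carries ground truth computed by
`oracle_outputs()`, a deliberately naive implementation — explicit loops,
least squares by hand-written normal equations, no helpers shared with the
engine — so engine and oracle form genuinely independent routes to the same
numbers. The test suite requires agreement within 1e-9 relative on every
quantity across 100 random systems (2–10 commodities each, 20-year series;
small sizes keep the whole suite fast while exercising every code path).

What the generator does **not** emulate: the marginal distributions of real
commodity masses, correlations between nutrients within a food, trade
imbalances, or reporting artifacts such as balance residuals. Passing tests
therefore demonstrate that the mechanism is computed correctly, not that
the package reproduces any published headline number from real data; those
require the real inputs mapped to the package's schemas (a documented,
untested converter stub `fao_fbs_to_commodities()` sketches the mapping).

## Numerical choices

- Negative fitted baselines (declining series extrapolated forward) clamp
  to zero with a warning; a negative mass is meaningless.
- Share sums are validated to 1 ± 1e-9; the generator sets the last share
  to the exact complement so synthetic data passes at machine precision.
- Ranks are competition ranks (ties share the best rank; 1, 2, 2, 4), with
  ties in the *ordering* broken by ascending commodity id so output is
  deterministic. Rank numbers themselves are tie-break-independent.
- A nutrient no food supplies has an undefined contribution percentage:
  reported as `NA` in machine output and "No contribution" in the rendered
  table. A zero target yields an infinite adequacy sentinel (trivially
  adequate) rather than a division error.
- Printed percentages round half-up to integers; CSV outputs keep full
  precision (15 significant digits, enough for exact round-trips).
- Scenario multipliers of 1 are exact no-ops at the byte level of written
  outputs, a property the tests assert.

## Limitations

- Global only: no regional disaggregation of consumption or of milk-type
  composition differences.
- Availability, not intake: the model returns the maximum nutrition
  available after waste and losses, not what individuals eat.
- No feed/trade feedback: scaling an animal-product group does not scale
  feed demand.
- Mineral and vitamin bioavailability is not modelled (coefficient 1), so
  adequacy for minerals such as calcium is optimistic.
- No within-population distribution modelling: an adequacy ratio of 1 means
  supply equals the aggregate target, not that everyone is nourished.
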