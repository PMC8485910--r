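---
title: "Mass-balance modelling of food-system nutrient adequacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance modelling of food-system nutrient adequacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltafood)
```

## The model

`deltafood` answers a population-scale question: if a given food system's
output were shared equally across everyone, would it supply enough of every
essential nutrient — and not too much of any? It is a mass-balance model,
not an optimizer: scenarios go in, nutrient gaps and excesses come out, and
two scenarios can be compared side by side.

A scenario is stated at the level of food *groups* (cereals, dairy, fish,
...). The pipeline then proceeds in five stages:

1. **Disaggregation.** Group production is split into individual food
   items in proportion to each item's share of its group in the pooled
   multi-year commodity-balance history. The within-group composition of
   production is therefore fixed at its historical distribution; scenarios
   move groups, not items.
2. **Mass cascade.** Per item, farm-gate production is reduced by animal
   feed use, supply-chain losses, and nonfood uses (seed, biofuel,
   industrial), giving consumer availability; then by the inedible
   fraction (peels, bones), giving edible mass; then by in-home waste,
   giving consumed mass. Feed, loss and nonfood are all defined as
   fractions of farm-gate production (not sequential residuals), so the
   order of that trio cannot change the result; the inedible and in-home
   steps are genuinely sequential and applied in that order, since
   households discard edible food. Consumed mass is rescaled to
   grams/person/day using the scenario year's population and a 365-day
   year.
3. **Nutrient conversion.** Each item's allocation is multiplied by its
   nutrient densities (per 100 g edible portion). Protein and the
   indispensable amino acids are additionally multiplied by a
   food-specific digestibility coefficient in (0, 1]; all other
   nutrients use coefficient 1, because comparable absorption data do
   not exist across foods.
4. **Requirement weighting.** Dietary reference values vary by sex and
   age group; population counts vary by region, sex and age group. The
   target for the average citizen is the population-share-weighted mean
   of the stratum targets; lower and upper safe bounds are weighted with
   the same shares and reported only when every stratum carries them.
   Regions contribute weight only, as reference values are not regional.
5. **Reporting.** Per nutrient: percent of target, gap
   (`max(0, 100·(target − supply)/target)`), and excess above the upper
   safe bound where one exists. Gaps at or below 5% of target are kept in
   the report but flagged immaterial — differences that small are inside
   the model's accuracy. A parallel report converts the cascade's two
   waste flows into nutrient terms and splits each nutrient's waste
   between plant- and animal-origin foods.

### Feed coupling

Feed links plant production to animal production: removing meat from a
scenario frees the grain that fed it. Each feed item's baseline feed
tonnage is attributed across animal groups — proportionally to their
baseline production by default, or by an explicit attribution table — and
scenario feed demand scales each attributed share by the animal group's
scenario-to-baseline production ratio. Feed demand exceeding an item's
production is an infeasibility error, never a clamp: silent clamping hides
modelling mistakes.

### Iron and zinc under plant-based diets

Iron and zinc absorption is substantially lower from plant-based diets,
but food-by-food absorption data are too sparse to weight them like
protein. Instead the reference-value table may carry alternate
(higher) vegetarian and vegan targets for these nutrients. The diet mode
that selects them is detected from the scenario itself: a scenario is
*vegan* when every animal-origin group falls below 1% of its baseline
production, *vegetarian* when all meat/fish groups do but dairy or eggs
remain, *omnivore* otherwise. The 1% threshold (configurable) separates
deliberate exclusion from rounding noise; no threshold is dictated by the
underlying data. An explicit `diet_mode` in the scenario overrides
detection.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `weights` (baseline trend fit) | `"linear"` | year weights for the production extrapolation, rising 1 → 2 from oldest to newest year |
| `days_per_year` | 365 | converts annual tonnage to daily allocation |
| `material_threshold_pct` | 5 | gap percentage above which a gap is material |
| `diet_threshold` | 0.01 | fraction of baseline production below which an animal group counts as absent |
| waste multipliers | 1 | scenario scaling of supply-chain loss and in-home waste fractions |
| `nonfood_mode` | `per_capita_constant` | nonfood tonnage constant per person, or proportional to production |

The baseline year's production is extrapolated from the multi-year
history with a weighted least-squares line. The exact weighting scheme of
the original data pipeline is not published; the linear 1 → 2 ramp is this
package's documented stand-in, chosen because it favours recent years
while using the full history, and because *any* weighting reproduces an
exactly affine history exactly — which makes the choice testable
independently of the unknown "true" weights. `"uniform"` and fully custom
weight vectors are available.

Two further conventions deserve note. Item shares are derived from mass
pooled (summed) across all history years rather than from averaged yearly
shares, which keeps them well defined when an item produces nothing in
some years. Negative extrapolations clamp to zero with a warning: mass
non-negativity dominates trend fidelity.

## Numerical choices and degenerate inputs

* Mass conservation — production = feed + loss + nonfood + inedible +
  in-home waste + consumed — holds by construction and is asserted in
  tests to 1e-6 relative on every run.
* The nutrient closure identity (consumed supply + wasted nutrients =
  supply of the same scenario with both waste multipliers at 0) holds
  because waste accounting applies the same digestibility weighting and
  the same edible-fraction convention as consumed supply: supply-chain
  losses carry nutrients only in their edible fraction, since inedible
  matter carries no nutrients by convention.
* Regional in-home waste fractions collapse to one global fraction per
  group by population weighting across regions at the scenario year.
  A supply-weighted collapse would need regional supply data the schema
  does not carry, so it is not offered.
* Any negative intermediate mass, an effective waste fraction above 1, or
  feed demand above an item's production raises a classed
  infeasible-scenario error naming the item and stage.
* Populations are taken at the scenario year and interpolated linearly
  per stratum between tabulated years; a year outside the tabulated range
  is an error.
* Zero-target nutrients cannot occur (targets are validated positive);
  a nutrient supplied without any target yields a warning row with `NA`
  gap rather than a division error.
* Percentages are carried at full precision internally and rounded only
  for display.

## Synthetic worlds and what the tests show

No real commodity-balance, composition, reference-value or demographic
data ship with the package; all testing runs on generated miniature
worlds.

`make_analytic_world()` is fixed and seed-free: two groups (cereals:
wheat + maize; fish), exactly affine production histories with
proportional cereal histories, round fractions, and a 10,000-person
two-region population. Its baseline cascade has short closed forms,
derived by hand:

* 2018 production: wheat 1000 t, maize 500 t, fish 600 t (affine
  extrapolation is exact).
* Feed: wheat and maize each carry 100 t of baseline feed, all
  attributed to the fish group (600 t), so baseline ratios leave feed at
  100 t each.
* wheat: 1000 − 100 (feed) − 50 (5% loss) − 50 (nonfood) = 800 edible
  (nothing inedible); minus the population-weighted 14% cereal in-home
  waste → **688 t consumed**.
* maize: 500 − 100 − 50 − 0 = 350; minus 20% inedible → 280; minus 14%
  → **240.8 t**.
* fish: 600 − 60 − 0 = 540; minus 50% inedible → 270; minus 7% →
  **251.1 t**.

`make_world(seed, shape)` draws randomized worlds: production log-uniform
over [1e3, 1e7] t with mild trends and ±15% year noise, Beta(2, 8) feed /
Beta(2, 18) loss / Beta(1.5, 28) nonfood fractions jointly capped at 0.9,
Beta(2, 6) inedible fractions, digestibility uniform on [0.3, 1],
Beta(2, 18) in-home waste fractions (a few percent to ~15%, the span
reported for real food groups), and stratum-varying reference values with
alternate iron/zinc targets at 1.3–1.9× the default. The `mini` shape (4
groups / 8 items / 3 regions) keeps property tests fast; the `paper`
shape carries the full vocabulary sizes of the real data (15 groups, 121
items, 5 regions, 21 age groups, both sexes, 29 nutrients including 7
indispensable amino acids).

`oracle_evaluate()` recomputes everything by naive nested loops, sharing
no code with the pipeline (its trend fit even goes through `stats::lm()`
instead of the pipeline's closed-form normal equations). The core
acceptance property is pipeline ≡ oracle to 1e-9 relative across seeded
random worlds and scenarios; in practice agreement is at rounding level
(~1e-14). Property suites additionally assert mass conservation, nutrient
closure, monotonicity of consumed mass in both waste multipliers, exact
linearity of the cascade under proportional nonfood scaling, convexity of
weighted targets, affine-exact extrapolation, and byte-stable report
serialization. Test problem sizes (8-item worlds, 10 seeds) were chosen
so the full suite exercises every code path in under a minute.

What passing these tests does **not** show: anything about real data.
The generators emulate schemas and invariants, not the statistical
structure of real food systems — real commodity shares are far more
skewed, real waste fractions correlate across groups and regions, real
reference values are not independent across strata, and real nutrient
densities are strongly correlated within food groups. Conclusions about
the actual global food system require the real input tables, prepared to
the documented schemas.

## Known limitations

* Scenarios act on groups; within-group item composition is frozen at
  the pooled historical distribution.
* Equal distribution of food is assumed; regional or individual-level
  adequacy is out of scope by design — if adequacy fails under equal
  distribution it fails a fortiori under unequal distribution.
* Pre-farm-gate losses, trade flows and the environmental/economic
  dimensions of sustainability are not modelled.
* Digestibility weighting covers protein and the indispensable amino
  acids only; mineral and vitamin bioavailability is represented solely
  by the iron/zinc target switch, which approximates (for example)
  phytate effects only at the population level.
* The model reports what a system supplies, not what people choose to
  eat; it is explicitly not an optimization tool.
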