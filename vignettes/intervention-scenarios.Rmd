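---
title: "Modelling overlapping micronutrient interventions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling overlapping micronutrient interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortisim)
```

## The model and its assumptions

`fortisim` models a *single representative day* of eating for one
population cell — country (Benin or Ghana) × setting (urban or rural) ×
group (non-pregnant non-lactating women, NPNL, assumed body weight 55 kg;
pregnant or lactating women, PL, 65 kg). A day is a meal plan (6 meals
urban, 4 rural with larger portions) over dishes, each dish a list of
(food, grams as consumed). Daily intake of each of the six tracked
micronutrients — iron (mg), zinc (mg), vitamin A (µg RE), niacin (mg),
folate (µg), iodine (µg) — is the triple sum of portion multiplier ×
ingredient mass × per-100 g density, plus any supplement vector.

Assumptions inherited from this framing:

* **Point scenarios, not distributions.** There is no intake-distribution
  or EAR-cut-point prevalence modelling; each scenario is one arithmetic
  point compared against reference values.
* **As-consumed compositions.** Densities are for cooked/edible portions;
  no retention or cooking-loss model is applied.
* **Full adherence.** Fortified products are assumed adequately fortified
  and consumed as specified; a compliance fraction is deliberately out of
  scope.
* **No absorption modelling.** Bioavailability enters only through the
  choice of reference values (5% iron, and the zinc reference the intake
  tables themselves imply — see below), never as a transformation of
  intake.

## Interventions and their composition

Four layer types transform a base scenario:

1. **Biofortification** replaces a food's composition wholesale (maize
   porridge made from provitamin A maize at 6 ppm β-carotene = 0.5 µg
   RE/g; orange-fleshed sweet potato at 55 ppm = 4.2 µg RE/g).
2. **Fortification** adds converted nutrient mass to a vehicle's density.
3. **Food swaps** add a food (100 g mango, 76 g fried tilapia, 40 g
   voluntary-fortified biscuit) or replace one by another at identical
   mass (vegetable oil → red palm oil), conserving total grams exactly.
4. **Supplementation** adds a per-day vector: IFA = 60 mg iron + 400 µg
   folic acid; VAS = one 200,000 IU retinol dose. The single high dose is
   counted in full on the simulated day because the comparison of interest
   is the acute total against the UL; no amortization is attempted.

Layers apply in the fixed order biofortification → fortification → swaps
→ supplements. The order matters only for overlapping layers (fortifying a
food that a swap removes); for disjoint layers the total is
order-invariant, and tests assert this. Each layer's contribution is the
prefix difference intake(layers ≤ L) − intake(layers < L), so
contributions always telescope to total − base.

## Unit conversions

* **Retinol IU → µg RAE: factor 0.3.** This is the standard conversion and
  the only one under which the 200,000 IU post-partum dose equals exactly
  20 × the 3000 µg RAE/day UL, as the source arithmetic requires.
* **Retinyl palmitate mass → RAE: 550 µg RAE/mg**, configurable. The
  molar ratio gives ≈546; regulations quote 550. Nothing downstream is
  sensitive at the table's printed precision.
* **β-carotene → RE: default 12:1, per-food configurable.** The two
  published crop densities imply *different* factors (maize 6 ppm → 0.5
  µg RE/g is 12:1; sweet potato 55 ppm → 4.2 µg RE/g is ≈13.1:1), so the
  fixtures store the printed densities as per-food overrides rather than
  recomputing them from a single factor.
* **Iodate → iodine:** compound mass × iodine mass fraction from atomic
  masses (KIO₃ 0.593, NaIO₃ 0.641, Ca(IO₃)₂ 0.651).
* **"ppm" ≡ mg/kg ≡ µg/g; "g/t" ≡ mg/kg** throughout.

## Compound vs elemental fortification levels

Flour standards name compounds (ferrous fumarate, zinc oxide) without
stating whether levels are compound or elemental mass. Both readings are
expressible (`elemental_equivalent` flag). Calibrating against the
published fortified-minus-basal deltas decides it empirically: with the
Benin flour mass implied by the folate delta (121.2 g/day), the elemental
reading predicts an iron delta of 7.27 mg against the printed 7.1, while
the compound reading (× 0.328) predicts 2.38. The packaged fixtures
therefore read flour iron/zinc levels as elemental and record the residual
in each cell's manifest. Salt levels, by contrast, only reproduce the
printed iodine deltas as *compound* (iodate) mass.

## What the fixtures emulate — and what they do not

The source menus and the underlying food-composition table entries are not
available. Each cell is therefore represented as:

* one **calibrated composite basal food** whose per-100 g composition is
  back-calculated so the basal scenario reproduces that cell's published
  "Diet" row *exactly* at printed precision (1 decimal place), split over
  the meal pattern (1000 g/day urban over 6 meals, 1100 g/day rural over 4
  meals via portion multipliers);
* explicit **vehicle foods** — salt, vegetable oil, wheat-flour products
  (urban only), and for Ghana maize porridge and a snack set — whose
  masses are back-calculated from the fortified-minus-basal deltas: salt
  from iodine, flour from folate, oil from the vitamin A remainder
  (e.g. Benin urban: oil ≈ 109.9 g/day, salt ≈ 13.5 g/day, flour ≈
  121.2 g/day). Salt and oil masses so derived are high relative to
  consumption surveys; no published masses exist to confirm against, and
  the manifest flags them as derived.

A green fixture test therefore establishes that the *pipeline arithmetic*
reproduces the published rows given the published levels and reference
values — not that the composite resembles any real menu food-by-food.
Within-food heterogeneity, day-to-day variation, seasonality and energy
content are all outside the stated world.

Published rows that are internally inconsistent are **recorded, not
forced**: the Ghana rural fortified rows imply wheat-flour deltas although
flour is stated urban-only (the fixtures follow the urban-only rule and
record the deviations); the Ghana PL rural fortified row shows iron
*decreasing* and a zero oil vitamin A delta (that cell's oil mass
calibrates to 0 g/day); the VAS totals print 60 µg above dose + diet; one
IFA iron total prints 82.6 against 22.7 + 60 = 82.7. The
biofortification and food-swap rows are mutually inconsistent across
settings and are not calibration targets at all. Every residual lives in
the fixture manifest (`build_fixture(...)$manifest`,
`fixtures --out DIR` → `manifest.json`).

## Reference values

The reference registry is data-driven (CSV-round-trippable) so official
WHO/IoM values can be swapped in. The packaged set is back-calculated from
the published percentage cells and tagged as such, because the narrative
and the tables disagree in places:

* NPNL iodine UL: the stated 30 µg/kg × 55 kg rule gives 1650 µg/day, but
  every printed %UL cell back-calculates to ≈1100 µg/day; the fixture uses
  1100 and `iodine_ul()` implements the stated rule separately.
* Zinc: the text states 15% bioavailability (RNI 9.8 mg) but the cells
  back-calculate to the moderate-bioavailability RNI of 4.9 mg; 4.9 is
  used. PL zinc prints no usable %UL, so no UL is assessed for that group.
* PL iron EAR back-calculates to 40 mg/day, *above* the stated lactating
  RNI of 30 mg/day. Both are kept as printed; classification therefore
  checks above-UL first, then below-EAR, so an intake can be `above_UL`
  while still failing the EAR.
* Not every printed percentage is reproducible from the 1-dp intakes with
  any single reference value (e.g. NPNL zinc %EAR cells imply EARs from
  4.08 to 4.12); the registry reproduces every cell used by the acceptance
  criteria and the large majority of the rest.

## Numerical choices

* Percentages are rounded half-away-from-zero to integers and intakes to 1
  decimal place, matching table precision; **classification always uses
  unrounded values**, and renderers never re-round (JSON carries
  `raw_intake`).
* `above_UL` iff unrounded intake strictly exceeds the UL; intake exactly
  at the RNI with no UL is `adequate`.
* Composition tables are immutable; interventions return modified copies,
  and fortification tags the vehicle so re-applying the same spec is
  idempotent.
* Decimal commas in CSV input ("3,9") are normalized to dots.
* Randomized suites default to seed 20210722; the synthetic generator is
  fully seed-deterministic and restores the caller's RNG state.

## The independent oracle

`oracle_intake()` re-implements scenario resolution as a naive triple loop
over meals × dishes × ingredients on a plain copy of the food map, with
its own layer-application arithmetic; it shares only the unit-conversion
primitives (`to_ug_rae()`, `iodate_to_iodine()`). The acceptance suite
requires agreement with `compose_bundle()` to 1e-9 relative on 200 seeded
random bundles and on every fixture bundle.

## Known limitations

* The composite-basal representation cannot answer food-level questions
  (which dish carries the folate?) — only vehicle-level and total ones.
* Voluntary-fortified products (biscuit, red palm oil) are modelled as
  food swaps carrying their own composition, not as fortification specs,
  so their levels are not independently adjustable.
* A compliance/coverage-rate field is out of scope; all scenarios assume
  full adherence.
* Reference values are point estimates per group; no age- or
  trimester-specific refinement.
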