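# fortisim

Scenario simulation of micronutrient interventions for women of
reproductive age (WRA) in West African settings.

## The problem

National nutrition programs rarely act alone: mandatory fortification of
salt (iodine), vegetable oil (vitamin A) and wheat flour
(iron/zinc/folate/B vitamins) runs alongside biofortified crops,
iron–folic-acid (IFA) supplementation in pregnancy, high-dose post-partum
vitamin A supplementation (VAS), and voluntary-fortified products. Each
intervention is evaluated in isolation, but a woman receives their *sum*.
`fortisim` builds a representative day of eating for a population cell
(country × urban/rural × non-pregnant-non-lactating (NPNL) or
pregnant/lactating (PL)), layers interventions onto it, totals daily intake
of six tracked micronutrients — iron (mg), zinc (mg), vitamin A (µg RE),
niacin (mg), folate (µg), iodine (µg) — and compares the result against
dietary reference values to flag both inadequacy and risk of excess.

## The model

Daily intake is a linear functional of the diet. For a scenario with meals
*m*, dishes *d* and ingredients *i*,

```
intake_n = Σ_m Σ_d Σ_i  multiplier_md × grams_di × density_n(food_i) / 100  +  supplements_n
```

Interventions transform the terms: **fortification** adds converted
nutrient mass to a vehicle's density (e.g. 50 IU retinyl palmitate/g oil →
+15 µg RAE/g via 1 IU = 0.3 µg RAE; 35 mg KIO₃/kg salt → +20.76 µg
iodine/g via the 0.593 iodine mass fraction of KIO₃); **biofortification**
replaces a food's composition wholesale; **food swaps** add a food (one
100 g mango, 76 g fried tilapia, a 40 g fortified biscuit) or substitute
one for another at identical mass (vegetable oil → red palm oil);
**supplementation** adds a per-day vector (IFA: 60 mg Fe + 400 µg folic
acid; VAS: one 200,000 IU dose = 60,000 µg RAE counted on the simulated
day). Layers compose in a fixed order (biofortification → fortification →
swaps → supplements) and their marginal contributions always sum, with the
basal intake, to the total.

Coverage per nutrient is reported as %EAR, %RNI and %UL (estimated average
requirement, recommended nutrient intake, upper limit), with a risk class:
`below_EAR`, `EAR_to_RNI`, `adequate`, or `above_UL` whenever the
unrounded intake exceeds the UL. Iron references use 5%-bioavailability
values (RNI 58.8 mg/day for NPNL women) with the IoM UL of 45 mg/day; the
PL iodine UL follows the 40 µg/kg/day × 65 kg body-weight rule (2600
µg/day).

The packaged Benin/Ghana fixtures stand in for unavailable appendix menus:
each cell is a calibrated composite basal food plus explicit vehicle foods
whose masses are back-calculated from published intake rows (details and
every recorded inconsistency are in `vignettes/intervention-scenarios.Rmd`
and each fixture's manifest).

## Worked example

Fortified diet plus supplementation (IFA + post-partum VAS) for urban
Ghanaian pregnant/lactating women:

```r
library(fortisim)
fx  <- build_fixture("ghana", "urban", "pl")
res <- compose_bundle(fx$bundles$diet_fortification_supplementation, fx$table)
cov <- coverage(res$total, fx$refs, fx$scenario$group)
writeLines(render_report(
  report_rows("ghana_urban_pl:diet_fortification_supplementation", cov),
  "markdown"))
```

```
| scenario | nutrient | intake | %EAR | %RNI | %UL | flag |
|---|---|---|---|---|---|---|
| ghana_urban_pl:diet_fortification_supplementation | iron | 70.9 | 177 | 236 | 157 | UL! |
| ghana_urban_pl:diet_fortification_supplementation | zinc | 7.0 | 121 | 100 | - | RNI |
| ghana_urban_pl:diet_fortification_supplementation | vitamin_a | 60725.0 | 10616 | 7591 | 2024 | UL! |
| ghana_urban_pl:diet_fortification_supplementation | niacin | 8.9 | 63 | 49 | 25 |  |
| ghana_urban_pl:diet_fortification_supplementation | folate | 710.0 | 148 | 118 | 71 | RNI |
| ghana_urban_pl:diet_fortification_supplementation | iodine | 103.3 | 72 | 52 | 4 |  |
```

Reading the rows: the 60 mg IFA iron dose alone pushes total iron to 70.9
mg/day, 157% of the 45 mg UL, while the single 200,000 IU VAS dose is ~20×
the 3000 µg RAE vitamin A UL (2024% here); folate and zinc reach their
RNIs without breaching limits, and niacin and iodine stay below even the
EAR — adequacy and excess risk coexist in the same scenario.

The same pipeline is scriptable:

```sh
Rscript inst/cli/fortisim simulate --country ghana --setting urban --group pl \
    --scenario diet_fortification_supplementation --format markdown
Rscript inst/cli/fortisim matrix --country benin --format csv --out benin.csv
Rscript inst/cli/fortisim fixtures --out fixtures/
```

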