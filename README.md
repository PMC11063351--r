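# dishlabel

Nutrition calculation and labeling for cooked catering dishes.

Restaurant dishes rarely come with trustworthy nutrition labels: the raw
ingredients are known, but cooking changes both the dish's mass (water
uptake or loss, absorbed oil) and, effectively, the nutrient content per
100 g that a label must declare. Laboratory analysis of every dish is far
too expensive, and naive recipe summation ignores cooking altogether.
`dishlabel` implements a calculation model for this problem, aimed at
food-service nutritionists, label compliance teams and nutrition
informatics developers. It provides:

* a **raw-material composition database** with subclass *representative
  values* (unweighted means), so that novel or regional ingredient
  varieties missing from a food composition table resolve to their food
  type's mean composition;
* a **raw-to-cooked ratio database** (44 measured dishes), where
  `ratio = raw edible mass / cooked mass` (ratio < 1: the dish gains
  mass, e.g. rice absorbing water; ratio > 1: it loses mass);
* a **label engine** computing per-100 g-cooked content of fat, protein,
  carbohydrate and sodium, plus energy and NRV%;
* a **correction-factor model** that screens calculated-vs-detected
  nutrient ratios and derives multiplicative cooking-method corrections.

## The model

For a dish with ingredients *i* = 1..n of edible raw mass *m_i* (g) and
per-100 g raw nutrient content *c_i*, cooked weight *W* (measured, or
estimated as total raw input mass divided by the raw-to-cooked ratio *R*
of the main ingredient), correction factor *f* and seasoning contribution
*S* (oil fat, salt/soy-sauce/chicken-essence sodium, sugar carbohydrate):

    C (g/100 g cooked) = ( Σ_i  c_i · m_i / 100 · f  +  S ) / W × 100

Nutrient mass is conserved from raw to cooked, so with the estimated
cooked weight the single-ingredient case collapses to the familiar
`C = c · R · f`. Energy uses configurable conversion factors (default
protein 17, fat 37, carbohydrate 17 kJ/g) and NRV% is
`100 · amount / daily reference` (defaults: energy 8400 kJ, protein 60 g,
fat 60 g, carbohydrate 300 g, sodium 2000 mg).

Correction factors are fit from paired calculated/detected tables: a
(category, method, nutrient) key whose calculated/detected ratio falls at
or beyond the screening bounds (≤ 0.5 or ≥ 2, on unrounded ratios) gets an
active factor equal to the mean of detected/calculated over its cells.

## Worked example

```r
library(dishlabel)

comp <- data.frame(
  id = c("rice_01", "egg_01"),
  name = c("rice (polished)", "hen egg"),
  general_category = c("grain", "egg"),
  subclass = c("rice", "egg"),
  edible_fraction = c(1, 0.88),
  water_g = c(13.3, 74.1), protein_g = c(7.9, 13.3),
  fat_g = c(0.8, 8.8), carbohydrate_g = c(77.2, 2.8),
  ash_g = c(0.6, 1.0), sodium_g = c(0.002, 0.131))
db <- composition_db(read_composition_table(comp))

fried_rice <- dish(
  "Egg fried rice", "Stir-frying",
  ingredients = data.frame(food = c("rice_01", "egg_01"),
                           raw_mass_g = c(150, 60)),
  seasonings = data.frame(kind = c("oil", "salt"), mass_g = c(15, 2)))

compute_label(fried_rice, db)
#> Nutrition label: Egg fried rice (stir_frying)
#> Cooked weight: 457.9 g (estimated)
#>                     Per 100 g     NRV%
#> Energy                  674 kJ       8
#> Protein                  4.1 g       7
#> Fat                      4.5 g       8
#> Carbohydrate            25.6 g       9
#> Sodium                  187 mg       9
```

The cooked weight comes from the packaged stir-fried-rice ratio (0.48):
(150 g rice + 52.8 g edible egg + 17 g seasonings) / 0.48 ≈ 457.9 g. Fat
includes the 15 g of cooking oil; sodium is dominated by the 2 g of salt
(0.786 g Na). Each per-100 g value is also expressed as a percentage of
its daily reference amount (NRV%).

Fitting and inspecting the correction model on the packaged measurement
tables:

```r
m <- correction_model(fixture_pairs())
m
#> Cooking-method correction model: 188 (category, method, nutrient) keys, 88 active
#> Screening bounds: ratio <= 0.5 or >= 2 (on unrounded ratios); aggregation: mean of detected/calculated

validate_correction(fixture_pairs(), m)
#> Correction validation over 192 cells (MAE g/100 g, MAPE %):
#>      nutrient mae_before mae_after mape_before mape_after error_increased
#>           fat       7.66      3.43       71.15      23.67           FALSE
#>       protein       6.82      3.41       49.19      19.11           FALSE
#>  carbohydrate      12.56      4.34       72.74      21.16           FALSE
#>        sodium       0.27      0.05       73.41      10.62           FALSE
#>       overall       6.83      2.81       66.62      18.64           FALSE
```

A command-line interface wraps the same functions (`exec/dishlabel` after
installation): subcommands `label`, `repvalues`, `ratio-table`,
`derive-corrections`, `validate`, `fixtures` and `synth`.

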