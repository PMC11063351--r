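---
title: "Methods: the dishlabel calculation and correction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dishlabel calculation and correction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dishlabel)
```

## The problem

A nutrition label for a cooked dish declares nutrient content per 100 g
of the dish *as served*. Recipe data, however, describe *raw* ingredients
per 100 g of *edible raw* portion. Between the two sit three effects:
inedible parts are discarded (edible fraction), cooking changes the
dish's mass (water uptake or loss, rendered or absorbed fat), and cooking
redistributes or destroys nutrients in ways simple mass bookkeeping does
not capture. `dishlabel` models the first two effects mechanistically
and absorbs the third into empirically derived correction factors.

The modeled nutrients are total fat, protein, carbohydrate and sodium —
the mandatory and principal optional items of Chinese catering-food
nutrition labeling — all carried internally in g/100 g (sodium included;
label output converts to mg).

## Composition database and representative values

Ingredients are organized in a two-tier hierarchy: a general category
(grain, meat, fish, egg, vegetable) and a subclass (rice, chicken breast,
potato, ...). For each tier the package computes *representative values*:
the unweighted arithmetic mean of every nutrient over the group's
records. The mean is unweighted because no defensible weighting (market
share, regional production) is available at the composition-table level;
records missing an optional nutrient are skipped for that nutrient rather
than imputed, and the per-nutrient count is reported alongside
`n_members`.

Ingredient resolution (`resolve_ingredient()`) is deliberately
conservative: an exact name/id match returns the record's own values;
otherwise a declared subclass returns the subclass representative;
otherwise a declared general category returns the category
representative; otherwise resolution fails loudly with the list of known
subclasses. No fuzzy string matching is attempted — silently matching
"rice wine" to "rice" would be worse than an error. The returned vector
is always bit-identical to a stored record or representative; resolution
never interpolates.

`carbohydrate_by_difference()` implements the proximate rule
`carbohydrate = total mass − water − ash − protein − fat`. Negative
results within 0.5 g are clamped to zero with a diagnostic (proximate
analysis noise routinely produces small deficits); larger deficits are
treated as inconsistent input, not noise.

## Raw-to-cooked ratios

The yield ratio is defined as **raw edible mass ÷ cooked mass**. The
orientation matters and is easy to get backwards: steamed rice has ratio
0.49 (the cooked dish weighs twice the raw rice), deep-fried potato 1.53
(the fries weigh a third less). The packaged table holds 44 dishes
spanning seven cooking methods (steaming, boiling, stir-frying,
deep-frying, roasting, stewing, quick-boiling); printed method labels
such as "Stewing (with soy sauce)" or "Deep frying" normalize to
canonical tokens. When several measured dishes share a (food, method) key
their ratios are averaged arithmetically. A missing key is an error by
default; `assume_unity = TRUE` substitutes 1.0 with a warning for
workflows that prefer degraded output over none.

## The label engine

The engine implements a mass-conservation reading of the calculation
model: nutrient mass in equals nutrient mass out,

$$C = \frac{\sum_i c_i\, m_i / 100 \cdot f_{(k,\mathrm{method},\mathrm{nutrient})} + S}{W} \times 100,$$

where $m_i$ is the edible raw mass of line $i$ (raw mass × edible
fraction), $c_i$ its per-100 g raw content, $f$ the correction factor for
the line's category and the dish's cooking method (1 when no correction
model is supplied), $S$ the seasoning contribution and $W$ the cooked
weight. As printed in its source material the formula carries the yield
ratio in the numerator *and* the cooked weight in the denominator;
applied literally with a ratio-derived weight this would double-count the
yield. The conservation reading reproduces the intended one-line formula
`C = c × R × f` exactly when $W$ is estimated as raw input mass ÷ ratio,
and uses the measured cooked weight unchanged when one is provided
(measured weight wins over the ratio estimate when both exist).

Choices the formula's prose leaves open, fixed here:

* **Mixtures.** The cooked weight of a multi-ingredient dish is estimated
  with the *main ingredient's* ratio — the line with the largest edible
  raw mass — applied to the total raw input mass including seasonings.
  Per-ingredient yields for mixed dishes are not separately measurable.
* **Correction factors are applied per line**, keyed by each line's
  category and the dish's method. For single-category dishes this equals
  scaling the totals; for mixtures it is the faithful reading of a factor
  that sits inside the per-food product.
* **Seasonings** contribute fat (oil), sodium (salt 39.3 g Na/100 g by
  NaCl stoichiometry, soy sauce 5.8, chicken essence 20) and — because
  sugar is one of the weighed seasonings — sugar's carbohydrate
  (toggleable via `sugar_carbohydrate`). Vinegar and fermented curd
  contribute none of the modeled nutrients. The oil uptake fraction
  defaults to 1: oil not absorbed by the food still ends up in the served
  dish. All compositions are configuration, not constants.
* **Energy** defaults to the Chinese labeling convention 17/37/17 kJ/g
  for protein/fat/carbohydrate; Atwater 4/9/4 kcal factors are available
  through `energy_of(..., factors =, unit = "kcal")`, with kJ/kcal
  interconversion at 4.184.
* **NRV references** default to energy 8400 kJ, protein 60 g, fat 60 g,
  carbohydrate 300 g, sodium 2000 mg; `nrv_basis` selects whether NRV%
  is computed from per-100 g values (label default) or whole-dish totals.
* **Rounding** is display-only: 1 decimal for g/100 g, integers for kJ,
  mg sodium and NRV%. Internal arithmetic is never rounded.

Two invariants pin the engine down and are enforced in the tests: with
unit factors and no seasonings, `per_100g × W / 100` equals the nutrient
sum exactly (conservation), and scaling every mass and the measured
weight by k leaves per-100 g values unchanged (homogeneity).

## Correction factors

Calculated and laboratory-detected per-100 g values for the same dishes
are paired (the packaged tables align by row position, since dish and
method labels drift between them) and the ratio
calculated/detected is computed per dish and nutrient. A cell is
*flagged* when the ratio is ≤ 0.5 or ≥ 2 — bounds inclusive, evaluated on
the **unrounded** ratio (a cell printed "0.50" may owe its flag to an
unrounded 0.4967) — or degenerate: calculated 0 gives ratio 0 (flagged),
detected 0 with calculated > 0 gives an undefined, flagged cell.

`correction_model()` pools cells per (category, method, nutrient) key.
Keys with at least one flagged cell become *active* with
`factor = mean(detected/calculated)` over the key's usable cells
(calculated > 0); mean is the default aggregation, median is available
for robustness against a wild cell. Unflagged keys keep factor 1 and stay
inactive — the model corrects only where screening shows the calculation
is off by at least two-fold, rather than chasing noise everywhere. A
flagged key with no usable cell (e.g. all calculated values zero) yields
a factor-underivable warning and factor 1. On training data a
singleton-support factor reproduces its detected value exactly; this is a
test anchor, not a claim of predictive accuracy.

`validate_correction()` reports mean absolute error and mean absolute
percentage error (over cells with detected > 0) before and after
correction, per nutrient and overall, and flags any nutrient whose error
increased. Display rounding throughout the ratio table is half-up to two
decimals (`round_half_up()`), matching the print convention of the
packaged tables; base R's round-half-to-even would disagree on tie cells.

## Packaged measurement tables

Five plain-CSV tables ship with the package: the 15-row sampling plan,
the 44-dish yield-ratio table, the 48-dish detected table (means with
SDs; the SDs are carried but unused by computation), the 48-dish
calculated table and the 48-dish printed ratio table with its star
flags. Known quirks are preserved verbatim rather than reconciled: the
sampling plan's row counts sum to 144 while its printed total says 150;
one fish category is labeled "Scallops" in the detected table but
"Hairtail" in the calculated one; one shrimp dish's method differs
between tables. Alignment is therefore by row position, with category and
method taken from the calculated table. `printed_ratio_agreement()`
recomputes all 192 ratio cells from the calculated/detected tables and
compares values (±0.01 after rounding) and flags against the printed
table.

## Synthetic data

The generators (`synthetic_spec()`, `generate_synthetic_composition()`,
`generate_synthetic_pairs()`) emulate the calibration design at
configurable size. Composition records are independent normal draws
around per-subclass target means (SD 10% of the mean), truncated at 0;
water and ash are left absent because independent draws of six proximates
would routinely violate the proximate-sum constraint that real
composition rows satisfy. Paired observations set
`detected = calculated / bias × (1 + ε)`, ε ~ N(0, noise_sd), so the
recoverable correction factor is 1/bias by construction. A seed is
mandatory and fully determines the output.

What the synthetic data do *not* emulate: correlations between nutrients
within a food, heteroscedastic laboratory error, method-dependent bias
structure, and the heavy-tailed composition of real food groups. Passing
the recovery tests therefore shows the estimator is correct under the
stated generative model, not that real kitchen data are this well
behaved.

## Problem sizes and numerical tolerances

The property suites run at sizes chosen to make the checks sharp yet
quick: 1,000 random dishes for the conservation and closed-form
invariants (tolerance 1e-9, far below any nutritionally meaningful
scale), 20 dishes with 5% multiplicative noise for bias recovery
(recovered factor within 5% of 1/3), and 200 records per subclass for
representative-value recovery (within 3 standard errors of the
generating mean, and exactly equal to an independently coded brute-force
mean). Screening-table reproduction covers all 192 cells of the packaged
tables.

## Known limitations

* Correction factors are pooled per (category, method, nutrient) from
  very few dishes — often a single one — and carry no uncertainty
  intervals; they are calibration constants, not estimates with standard
  errors.
* The yield-ratio database covers the measured (food, method) pairs only;
  the package refuses to extrapolate (or substitutes 1.0 only on explicit
  request).
* Vitamins, minerals other than sodium, sugar as a separate analyte, and
  serving-size arithmetic beyond per-100 g are out of scope.
* Exact name resolution plus declared-class fallback is intentionally
  strict; multilingual or fuzzy dish-name normalization belongs in a
  layer above this package.
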