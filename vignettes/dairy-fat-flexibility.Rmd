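---
title: "Modeling dairy fat flexibility in the USDA 2000-kcal eating pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dairy fat flexibility in the USDA 2000-kcal eating pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairyflex)
```

## The question and the method

The USDA's Healthy U.S.-Style Eating Pattern (HUSEP) recommends three daily
cup-equivalents of low-fat or fat-free dairy for everyone aged nine and
older. dairyflex implements the food-pattern-modeling workflow used to ask
whether one of those servings could instead be a reduced- or whole-fat dairy
food without pushing the 2000-kcal pattern past its calorie, saturated-fat
(10% of calories) and sodium (2,300 mg/d CDRR) limits.

The workflow has four stages, each a module of this package:

1. **Composites.** A *dairy food composite* is a single per-serving nutrient
   profile formed as a consumption-share-weighted average of representative
   milk, cheese and yogurt profiles. For a recipe with foods $i$, raw shares
   $w_i > 0$ and per-cup profiles $x_i$ (vectors over the fixed 34-nutrient
   panel), the composite is
   $$c = \sum_i \frac{w_i}{\sum_j w_j}\, x_i .$$
   The shipped shares are the NHANES 2013–2016 proportions 47.76% milk,
   47.30% cheese, 4.93% yogurt — which sum to 99.99, which is why
   normalization divides by the actual sum rather than asserting 100.
2. **Substitution.** The non-dairy remainder of the reference pattern is
   $r = T_{\mathrm{ref}} - s\,c_{\mathrm{ref}}$ with $s = 3$ servings of the
   2015 USDA dairy composite, and a modeled pattern with substitution plan
   $\{(c_k, s_k)\}$, $\sum_k s_k = s$, is
   $$T = r + \sum_k s_k\, c_k .$$
   Nothing else in the pattern is adjusted; that is the point of the
   exercise (energy is allowed to drift upward and is reported).
3. **Percent change.** Each model is compared with the fat-free baseline
   (model 1, three servings of the updated fat-free composite A) as
   $100\,(T - T_1)/T_1$ per nutrient, computed on unrounded totals and
   displayed at one decimal. Changes of 10% and 20% are tiered using the
   U.S. labeling "good source" / "excellent source" cutoffs.
4. **Goal evaluation.** Day-level totals are divided by Dietary Reference
   Intake goals (RDA/AI/UL, plus the 2000-kcal energy goal) for two sample
   groups, females 19–30 and males 51+, and macronutrient percent of energy
   uses Atwater factors 4/4/9 kcal/g (every fat class at 9; alcohol is not
   modeled). Saturated fat is judged on the integer display value — a
   pattern displaying 10 is *at* the limit, not over it — and sodium flags
   when the amount strictly exceeds 2,300 mg.

## The nutrient panel and units

The panel is fixed to the 34 rows of the published day-level tables:
energy through the fatty-acid subclasses and cholesterol, nine minerals,
eleven vitamins, and fiber. Units are stored exactly as printed even where
the printed header is unconventional (selenium, vitamin B-12 and vitamin K
print "mg" though the magnitudes are conventionally µg; vitamin D is in IU;
vitamin A in µg RAE). Amounts are treated as opaque quantities in those
units: there is no IU↔µg conversion, and energy is a panel entry, never
recomputed from the macronutrients. Each suspicious unit carries a
`unit_note` in the panel fixture. The DRI table uses the same conventions,
so percent-of-goal ratios are unit-consistent by construction.

Dairy contributes no fiber, so the composite fiber value is exactly zero.
Other nutrients missing from a profile default to zero only under an
explicit `fill_missing = "zero"` policy, with a warning naming them.

## Printed inputs, rounding, and what "reproduces" means

The package's reference inputs are the *printed* composite table and the
printed USDA pattern column — themselves display-rounded. Recomputing a
model total $T = T_{\mathrm{usda}} - 3c_{\mathrm{ref}} + \sum_k s_k c_k$
touches one day-level cell and six composite servings, so the worst-case
inherited error is $0.5\,(1 + 3 + 3) = 3.5$ units of the last printed
digit. Ratios amplify this further: a ±0.35 mg uncertainty on a riboflavin
total divided by a 1.1 mg RDA is ±32 integer points of %RDA.

`reproduce_reference_tables()` therefore reports two verdicts per cell:

- `within_printed_unit`: the recomputed display value is within one unit of
  the last printed digit — true for 73 of 75 reconstructible totals cells
  (the exceptions are the two vitamin E cells, where printed composite
  inputs of 0 and 0.1 mg AT carry almost all their value as rounding), for
  38 of 50 percent-change cells, and for 111 of 138 goal-grid cells;
- `within_input_rounding`: the difference is inside the propagated
  worst-case bound above — true for every reconstructible cell of every
  table, which is the guarantee the arithmetic actually provides.

The headline anchors are exact: model 1 energy 2,006 kcal and sodium
2,378 mg (a 591 mg increase over the pattern's 1,787 mg), model 2 energy
2,055 kcal and sodium 2,353 mg, model 3 sodium 2,366 mg and calcium
1,624 mg, the 2.4% energy and −1.9% protein changes, and the model 1 goal
cells (saturated fat 8% of kcal, sodium 103% of the UL, calcium 149% of
the RDA for females 19–30). These land exactly because the underlying
printed cells happen to be integers with no fractional part to lose.

Nutrients with no printed composite values at all — the fatty-acid
subclasses (MUFA, PUFA, linoleic/linolenic, EPA, DHA, stearic acid), iron
and copper — are marked `reconstructible = FALSE` in the panel and get `NA`
verdicts: the published models clearly used non-zero composite values for
them (their model columns vary), but those values were never printed, so no
pipeline driven by printed inputs can recover them. Fiber is the one
nutrient absent from the composite table that *is* reconstructible, because
its composite value is genuinely zero. Two printed percent-change cells
("30" for model 4 vitamin A and "27" for model 7 energy, both inconsistent
with neighboring magnitudes) are stored verbatim with a `suspected_typo`
flag and excluded from comparisons.

## The DRI table

The publication does not print its DRI constants. They are encoded for the
two sample groups and every value was cross-checked by back-computing
`goal = amount / (percent/100)` from matched printed cells: calcium
1000/1200 mg, iron 18/8 mg, magnesium 310/420 mg, phosphorus 700 mg,
potassium AI 4,700 mg (the 2005-era AI — the only value consistent with
the printed 76% — not the 2019 revision), sodium UL 2,300 mg, zinc
8/11 mg, selenium 55, copper 0.9 mg, vitamin A 700/900 µg RAE, vitamin E
15 mg AT, vitamin D 600 IU, vitamin C 75/90 mg, thiamin 1.1/1.2 mg,
riboflavin 1.1/1.3 mg, niacin 14/16 mg, B-6 1.3/1.7 mg, B-12 2.4,
choline AI 425/550 mg, vitamin K AI 90/120 µg, protein 46/56 g,
carbohydrate 130 g, fiber AI 28 g, linoleic AI 12/14 g, linolenic AI
1.1/1.6 g. Choline and vitamin K are AIs although the printed grid labels
those rows "% RDA"; the fixture keeps the correct goal type with a note.
Sodium appears twice in the configuration — as the UL behind the "% UL"
rows and as the CDRR behind the threshold flag — because the two framings
are conceptually distinct even though both are 2,300 mg here. The
current-mean-sodium context value is 3,410 mg/d (the value used in the
source's discussion; its abstract says 3,440 — the fixture carries the
former).

## Display rounding

All display rounding is half *away from zero* (2.44 → 2.4, 46.7 → 47,
7.72 → 8), not banker's rounding: it is the convention that reproduces
every checked printed cell. `round_half_up()` nudges by 1e-8 before
truncating so decimal literals stored just under a tie (10.45 as
10.4499…) still round up; the nudge is far below any meaningful nutrient
resolution. Rounding happens only in `round_for_display()`, report
writers, and the display columns of reports — never inside arithmetic —
and is idempotent.

## The synthetic generator

Individual per-food FNDDS profiles are not published, so property tests
and the single-food plans run on synthetic records.
`generate_food_table()` draws per-cup-equivalent profiles for every
(milk/cheese/yogurt) × (fat-free/low-fat/reduced-fat/whole) cell:
positive nutrient centers, loosely calibrated to the published composite
magnitudes, get independent log-normal noise (`sdlog = 0.15` by default,
roughly ±15% — a plausible between-product spread), which keeps every
amount non-negative; fat-linked nutrients scale with a tier multiplier
(whole = 1, reduced-fat = 0.6, low-fat = 0.3, fat-free = 0.05 of the
whole-tier fat center) through fixed fatty-acid fractions of dairy fat,
so the whole tier's saturated fat stochastically dominates the fat-free
tier's. `generate_consumption_shares()` draws positive shares from a
symmetric Dirichlet scaled to total 100, mimicking the structure (not the
distribution) of the NHANES share estimation; the concentration parameter
defaults to 5, giving realistically unequal shares. Each call uses one
seeded stream via `withr::with_seed`, records the seed in its output, and
leaves the global RNG untouched.

Four stand-in records are drawn under the real food codes of the
unpublished single foods (whole/reduced-fat milk and cheese) so the
single-food substitution plans can run end to end; their descriptions say
"SYNTHETIC non-authoritative" and nothing computed from them is ever
compared against published values. The generator makes no attempt to match
real NHANES consumption distributions or FNDDS values, so passing property
tests demonstrate the algebraic contracts (convexity, conservation,
determinism), not nutritional realism.

## Numerical choices

- Composite weights must be strictly positive; an empty recipe is an error.
- Panel mismatches error naming the first differing nutrient; plans whose
  servings do not sum to the replaced dairy servings (3 cup-equivalents)
  error with both numbers.
- A negative non-dairy remainder errors naming the nutrient; magnitudes
  below 1e-9 are clamped to zero first to absorb float noise in decimal
  subtraction.
- Percent change with a zero baseline is flagged `applicable = FALSE` and
  reported `NA`, never computed.
- Exact identities (conservation, permutation/scale invariance) are tested
  at 1e-12; oracle comparisons at 1e-9 relative.
- Serving counts are reals, anticipating the 2½-serving child patterns,
  though every shipped plan uses integers.

## Problem sizes in the test-suite

The property suite uses 200 randomized composite recipes over a 64-record
synthetic table for oracle/convexity/invariance checks, 100 seeded
replicates of the synthetic end-to-end round trip, a 1,012-record table
for the fat-tier Monte-Carlo check, and 25-iteration loops for the profile
ring laws — sizes chosen so the whole suite is a desk-scale computation
while still exercising each contract across many draws.

## Limitations

- The whole exercise is theoretical food-pattern modeling on printed
  aggregate inputs, not an analysis of observed diets.
- Cells driven by unprinted composite values cannot be reproduced at all,
  and reproductions of printed cells inherit up to 3.5 last-digit units of
  input rounding (amplified in ratio-valued grids); the package reports
  both verdicts rather than pretending to a precision the inputs cannot
  support.
- Models 4–7 (single foods) run only on clearly-labeled synthetic
  stand-ins; only the three composite-based models are compared with
  published cells.
- Only the two adult sample groups are configured; no child, adolescent,
  pregnancy or lactation DRI sets, no added-sugars accounting beyond the
  120-kcal discretionary-calorie constant, and no re-optimization of the
  non-dairy remainder to hold energy constant.
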