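# dairyflex

Food pattern modeling of **dairy fat flexibility**: can one of the three
daily dairy cup-equivalents in the USDA 2000-kcal Healthy U.S.-Style
Eating Pattern (HUSEP) be a reduced- or whole-fat food while the pattern
stays within its calorie, saturated-fat (≤10% of calories) and sodium
(2,300 mg/d CDRR) limits?

The package is for nutrition researchers and dietary-guidance modelers.
It rebuilds the whole workflow from printed reference tables:

- **Consumption-weighted dairy composites.** A composite is a per-serving
  profile `c = Σᵢ (wᵢ/Σⱼwⱼ) xᵢ` over a fixed 34-nutrient panel, where the
  `wᵢ` are NHANES consumption shares (47.76% milk, 47.30% cheese, 4.93%
  yogurt) and the `xᵢ` per-cup-equivalent food profiles. The four
  published composites (the 2015 USDA composite and the updated fat-free
  A, reduced-fat B and whole-fat C) ship as fixtures.
- **Serving substitution.** The non-dairy remainder
  `r = T_ref − 3·c_ref` is held fixed and plans `T = r + Σₖ sₖ cₖ`
  (`Σ sₖ = 3`) swap dairy servings: model 1 is 3×A (the baseline), model 2
  is 2×A + 1×B, model 3 is 2×A + 1×C, models 4–7 substitute single milk or
  cheese foods.
- **Evaluation.** Per-nutrient percent change vs the baseline model
  (10/20% "good/excellent source" tiers), percent of DRI goals (%RDA, %AI,
  %UL, % energy goal) for females 19–30 and males 51+, macronutrient % of
  calories via Atwater 4/4/9, and the saturated-fat / sodium threshold
  screen.
- **Synthetic data.** A seeded generator of FNDDS-like dairy records
  (milk/cheese/yogurt × fat tier, log-normal per-cup amounts) so every
  stage — including the single-food models, whose real profiles were never
  published — is testable offline.

## Worked example

```r
library(dairyflex)

m <- reference_models()          # models 1-3 from the printed inputs
m$model3
#> <pattern_model> model3: 2 x A + 1 x C
#>   2085 kcal, saturated fat 22.8 g, sodium 2366 mg per day

flag_meaningful_changes(percent_change(m$model3, m$model1))
#>     nutrient_id pct_change                   tier
#> 1     total_fat   14.22414      good-source-scale
#> 2 saturated_fat   32.55814 excellent-source-scale
#> 3   cholesterol   10.68049      good-source-scale
#> 4     vitamin_d   25.54406 excellent-source-scale

check_thresholds(m$model3$total)
#> <threshold_report> saturated fat 10% of kcal (within limit); sodium 2366 mg (exceeds CDRR)

g <- suppressWarnings(pct_of_goal(m$model3$total, "females_19_30"))
g[g$nutrient_id %in% c("calcium", "sodium", "vitamin_d"), ]
#>    nutrient_id amount goal_type goal      pct display
#> 7      calcium 1624.0       RDA 1000 162.4000     162
#> 12      sodium 2366.0        UL 2300 102.8696     103
#> 18   vitamin_d  351.9       RDA  600  58.6500      59
```

Swapping one fat-free serving for the whole-fat composite adds ~79 kcal
and pushes saturated fat to exactly the 10%-of-calories display limit
(within, not over), leaves calcium at 162% of the RDA, and keeps sodium
just above the CDRR — the same sodium exceedance the fat-free baseline
already has (2,378 mg), driven by the cheese share of consumption, not by
fat level.

`run_pipeline(run_config("out/"))` writes the model-totals,
percent-change, goal and threshold tables as CSV plus a JSON report with
the unrounded values behind every printed cell;
`reproduce_reference_tables()` compares every recomputed cell with its
printed counterpart and reports whether it is within one last-printed
digit and within the worst-case bound propagated from the rounding of the
printed inputs (see the vignette in `vignettes/` for why those differ).

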