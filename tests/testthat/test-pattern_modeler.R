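test_that("the non-dairy remainder matches direct arithmetic on printed cells", {
  rem <- profile_amounts(derive_remainder(reference_pattern()))
  expect_equal(rem[["sodium"]], 1787 - 3 * 202)   # 1181
  expect_equal(rem[["vitamin_k"]], 139 - 3 * 0)   # zero composite entry
  expect_equal(rem[["energy"]], 2003 - 3 * 77)    # 1772
  expect_true(all(rem >= 0))
})

test_that("inconsistent pattern/dairy inputs are rejected by nutrient name", {
  tiny <- usda_pattern_profile()
  tiny$amounts[["sodium"]] <- 100  # less than 3 x 202 mg of dairy sodium
  expect_error(reference_pattern(total = tiny), "sodium")
})

test_that("substitution plans reproduce the printed day-level anchors", {
  m <- reference_models()
  expect_equal(profile_amounts(m$model1$total)[["energy"]], 2006)
  expect_equal(profile_amounts(m$model1$total)[["sodium"]], 2378)
  expect_equal(profile_amounts(m$model2$total)[["energy"]], 2055)
  expect_equal(profile_amounts(m$model3$total)[["calcium"]], 1624)
})

test_that("plans must supply exactly the replaced dairy servings", {
  rem <- derive_remainder(reference_pattern())
  short <- substitution_plan("short", list(
    list(component = reference_composite("A"), servings = 2)))
  expect_error(apply_plan(rem, short, 3), "sum to 2, expected 3")
  expect_silent(apply_plan(rem, short, 2))
})

test_that("totals conserve: total - remainder equals the component sum", {
  rem <- derive_remainder(reference_pattern())
  plans <- shipped_plans()
  for (p in plans) {
    mod <- apply_plan(rem, p, 3)
    contrib <- Reduce(`+`, lapply(p$components, function(cm)
      cm$servings * profile_amounts(cm$profile)))
    expect_equal(profile_amounts(mod$total) - profile_amounts(mod$remainder),
                 contrib, tolerance = 1e-12)
  }
})

test_that("substituting the original dairy component back is a no-op", {
  ref <- reference_pattern()
  round_trip <- pattern_model(ref, substitution_plan("identity", list(
    list(component = reference_composite("USDA2015"), servings = 3))))
  expect_equal(profile_amounts(round_trip$total), profile_amounts(ref$total),
               tolerance = 1e-12)
})

test_that("element-wise larger components never decrease any total", {
  set.seed(31)
  rem <- derive_remainder(reference_pattern())
  for (i in 1:20) {
    lo <- random_profile()
    hi <- lo
    bump <- stats::runif(length(hi$amounts), 0, 10)
    hi$amounts <- hi$amounts + bump
    plan_lo <- substitution_plan("lo", list(
      list(component = reference_composite("A"), servings = 2),
      list(component = lo, servings = 1)))
    plan_hi <- substitution_plan("hi", list(
      list(component = reference_composite("A"), servings = 2),
      list(component = hi, servings = 1)))
    expect_true(all(
      profile_amounts(apply_plan(rem, plan_hi, 3)$total) >=
        profile_amounts(apply_plan(rem, plan_lo, 3)$total) - 1e-12))
  }
})

test_that("percent change uses unrounded totals and one-decimal display", {
  m <- reference_models()
  pc2 <- percent_change(m$model2, m$model1)
  expect_equal(pc2$display[pc2$nutrient_id == "energy"], 2.4)
  pc3 <- percent_change(m$model3, m$model1)
  expect_equal(pc3$display[pc3$nutrient_id == "protein"], -1.9)

  self <- percent_change(m$model1, m$model1)
  expect_true(all(self$pct_change[self$applicable] == 0))
})

test_that("zero-baseline nutrients are flagged, not divided", {
  rem <- derive_remainder(reference_pattern())
  zero_epa <- rem
  zero_epa$amounts[["epa"]] <- 0
  plan <- substitution_plan("p", list(
    list(component = reference_composite("A"), servings = 3)))
  base <- apply_plan(zero_epa, plan, 3)
  mod <- base
  mod$total$amounts[["epa"]] <- 0.07
  pc <- percent_change(mod, base)
  row <- pc[pc$nutrient_id == "epa", ]
  expect_false(row$applicable)
  expect_true(is.na(row$pct_change))
})

test_that("meaningful changes are tiered at the 10/20% labeling cutoffs", {
  m <- reference_models()
  fl2 <- flag_meaningful_changes(percent_change(m$model2, m$model1))
  expect_equal(fl2$tier[fl2$nutrient_id == "vitamin_d"], "good-source-scale")
  expect_false("energy" %in% fl2$nutrient_id)  # +2.4% is below scale

  fl3 <- flag_meaningful_changes(percent_change(m$model3, m$model1))
  expect_equal(fl3$tier[fl3$nutrient_id == "saturated_fat"],
               "excellent-source-scale")

  none <- flag_meaningful_changes(percent_change(m$model1, m$model1))
  expect_equal(nrow(none), 0L)
})

test_that("recomputed tables agree with print within propagated input rounding", {
  r <- reproduce_reference_tables()
  # every reconstructible cell sits inside the worst-case bound inherited
  # from the display rounding of the printed inputs
  expect_true(all(r$totals$within_input_rounding, na.rm = TRUE))
  expect_true(all(r$pct_change$within_input_rounding, na.rm = TRUE))
  # and the vast majority land within one printed last digit
  expect_gte(mean(r$totals$within_printed_unit, na.rm = TRUE), 0.95)
  calcium <- r$totals[r$totals$model == "model1" &
                        r$totals$nutrient_id == "calcium", ]
  expect_equal(calcium$computed_display, 1490)  # printed 1491, one unit off
  expect_true(calcium$within_printed_unit)
})
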