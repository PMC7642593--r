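test_that("generation is deterministic per seed", {
  cfg <- synthetic_config(seed = 11, n_foods_per_group = 2)
  a <- generate_food_table(cfg)
  b <- generate_food_table(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_food_table(synthetic_config(seed = 12, n_foods_per_group = 2))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  expect_equal(attr(a, "seed"), 11L)
  # stand-ins for the unpublished single foods ship clearly labeled
  expect_true(all(c("11111000", "11112110", "14410110", "14410120") %in%
                    a$food_code))
  expect_match(a$description[a$food_code == "11111000"],
               "SYNTHETIC non-authoritative")
  no_ref <- generate_food_table(cfg, include_reference_codes = FALSE)
  expect_false("11111000" %in% no_ref$food_code)
  # the generator leaves the global RNG stream alone
  set.seed(5); before <- stats::runif(1)
  set.seed(5); invisible(generate_food_table(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("fat tiers order saturated fat as intended", {
  big <- generate_food_table(synthetic_config(seed = 2024,
                                              n_foods_per_group = 84))
  expect_gte(nrow(big), 1000)
  sf <- big[["saturated_fat__g"]]
  expect_gt(mean(sf[big$fat_tier == "whole"]),
            mean(sf[big$fat_tier == "fat_free"]))
  expect_gt(mean(big[["total_fat__g"]][big$fat_tier == "whole"]),
            mean(big[["total_fat__g"]][big$fat_tier == "reduced_fat"]))
  expect_true(all(as.matrix(big[grep("__", names(big))]) >= 0))
})

test_that("degenerate configurations fail cleanly downstream", {
  empty <- generate_food_table(synthetic_config(seed = 1,
                                                n_foods_per_group = 0))
  expect_equal(nrow(empty), 0L)
  spec <- composite_spec("x", data.frame(food_code = "90100000",
                                         weight_percent = 1))
  expect_error(build_composite(spec, empty), "not present")
  expect_error(generate_consumption_shares(synthetic_config(seed = 1), empty),
               "empty")
  expect_error(synthetic_config(seed = 1, sdlog = 0), "sdlog")
})

test_that("consumption shares behave like a Dirichlet draw over 3 groups", {
  foods <- shared_food_table()
  spec <- generate_consumption_shares(synthetic_config(seed = 3), foods)
  expect_s3_class(spec, "composite_spec")
  expect_equal(sum(spec$components$weight_percent), 100, tolerance = 1e-9)
  expect_true(all(spec$components$weight_percent > 0))
  # high concentration concentrates shares near equality
  tight <- generate_consumption_shares(
    synthetic_config(seed = 3, consumption_concentration = 1e6), foods)
  expect_equal(tight$components$weight_percent, rep(100 / 3, 3),
               tolerance = 0.01)
  # same seed, same spec
  again <- generate_consumption_shares(synthetic_config(seed = 3), foods)
  expect_identical(again$components, spec$components)
})

test_that("fixing shares to the published values reproduces the weighting stage", {
  foods <- shared_food_table()
  milk <- foods$food_code[foods$group == "milk"][1]
  cheese <- foods$food_code[foods$group == "cheese"][1]
  yogurt <- foods$food_code[foods$group == "yogurt"][1]
  spec <- composite_spec("published shares", data.frame(
    food_code = c(milk, cheese, yogurt),
    weight_percent = c(47.76, 47.30, 4.93)))
  built <- build_composite(spec, foods)
  expect_equal(unname(built$normalized_weights),
               c(47.76, 47.30, 4.93) / 99.99)
  expect_equal(profile_amounts(built$per_serving),
               naive_composite_amounts(foods, spec), tolerance = 1e-9)
})

test_that("synthetic end-to-end run keeps conservation and convexity, 100 seeds", {
  rem <- derive_remainder(reference_pattern())
  cols <- paste0(nutrient_panel()$nutrient_id, "__", nutrient_panel()$unit)
  for (seed in 1:100) {
    cfg <- synthetic_config(seed = seed, n_foods_per_group = 1)
    foods <- generate_food_table(cfg)
    spec <- generate_consumption_shares(cfg, foods)
    comp <- build_composite(spec, foods)
    # convexity of the composite
    sub <- foods[match(spec$components$food_code, foods$food_code), cols]
    expect_true(all(profile_amounts(comp$per_serving) >=
                      apply(sub, 2, min) - 1e-9))
    expect_true(all(profile_amounts(comp$per_serving) <=
                      apply(sub, 2, max) + 1e-9))
    # conservation through a 2+1 substitution plan
    plan <- substitution_plan("synthetic", list(
      list(component = reference_composite("A"), servings = 2),
      list(component = comp, servings = 1)))
    mod <- apply_plan(rem, plan, 3)
    contrib <- 2 * profile_amounts(reference_composite("A")$per_serving) +
      profile_amounts(comp$per_serving)
    expect_equal(profile_amounts(mod$total) - profile_amounts(rem),
                 contrib, tolerance = 1e-12)
  }
})

test_that("shipped reference tables load, checksum-verified and complete", {
  fx <- load_fixtures(check = TRUE)
  expect_s3_class(fx, "reference_fixtures")
  expect_equal(fx$composites$composite_c[fx$composites$nutrient_id == "energy"],
               157)
  expect_equal(fx$usda_pattern$amount[fx$usda_pattern$nutrient_id == "sodium"],
               1787)
  g <- fx$goal_grid
  expect_equal(g$value[g$nutrient_id == "vitamin_d" & g$model == "model1" &
                         g$group == "females_19_30"], 47)
  # completeness: every panel nutrient has a printed total for models 1-3
  mt <- printed_model_table(c("model1", "model2", "model3"))
  counts <- table(mt$nutrient_id)
  expect_true(all(counts == 3))
  expect_setequal(names(counts), nutrient_panel()$nutrient_id)
  expect_false(any(is.na(mt$total)))
  # the two suspected-typo percent cells are flagged and only those
  flagged <- printed_model_table()[printed_model_table()$pct_change_flag ==
                                     "suspected_typo", ]
  expect_equal(nrow(flagged), 2L)
  expect_setequal(paste(flagged$model, flagged$nutrient_id),
                  c("model4 vitamin_a", "model7 energy"))
})
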