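test_that("weight normalization divides by the actual sum", {
  spec <- composite_spec("A", data.frame(
    food_code = c("11113000", "14410130", "11411300"),
    weight_percent = c(47.76, 47.30, 4.93)))
  fr <- normalize_weights(spec)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # the published shares sum to 99.99, not 100
  expect_equal(unname(fr[["11113000"]]), 47.76 / 99.99)

  expect_equal(unname(normalize_weights(
    composite_spec("x", data.frame(food_code = "1", weight_percent = 80)))), 1)
  expect_equal(unname(normalize_weights(
    composite_spec("x", data.frame(food_code = c("1", "2", "3"),
                                   weight_percent = c(1, 1, 2))))),
    c(0.25, 0.25, 0.5))

  expect_error(composite_spec("bad", data.frame(food_code = "1",
                                                weight_percent = 0)),
               "strictly positive")
  expect_error(composite_spec("bad", data.frame(food_code = character(),
                                                weight_percent = numeric())),
               "no components")
})

test_that("single-food and identical-profile composites are identities", {
  foods <- shared_food_table()
  one <- composite_spec("one", data.frame(food_code = foods$food_code[1],
                                          weight_percent = 55))
  c1 <- build_composite(one, foods)
  expect_equal(profile_amounts(c1$per_serving),
               profile_amounts(food_profile(foods, foods$food_code[1])))

  # three copies of the same profile under arbitrary weights
  same <- foods[c(1, 1, 1), ]
  same$food_code <- c("90000001", "90000002", "90000003")
  same <- dairyflex::read_food_table(
    { p <- tempfile(fileext = ".csv"); write_food_table(same, p); p })
  spec <- composite_spec("same", data.frame(
    food_code = same$food_code, weight_percent = c(3, 11, 86)))
  expect_equal(profile_amounts(build_composite(spec, same)$per_serving),
               profile_amounts(food_profile(same, "90000001")),
               tolerance = 1e-12)
})

test_that("composites match the brute-force weighted sum on 200 random recipes", {
  foods <- shared_food_table()
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    w <- stats::runif(n, 0.01, 60)
    spec <- random_spec(foods, n, w)
    built <- build_composite(spec, foods)
    oracle <- naive_composite_amounts(foods, spec)
    expect_equal(profile_amounts(built$per_serving), oracle,
                 tolerance = 1e-9)
    # convexity: inside the component-wise envelope
    cols <- paste0(nutrient_panel()$nutrient_id, "__", nutrient_panel()$unit)
    sub <- foods[match(spec$components$food_code, foods$food_code), cols]
    expect_true(all(profile_amounts(built$per_serving) >=
                      apply(sub, 2, min) - 1e-9))
    expect_true(all(profile_amounts(built$per_serving) <=
                      apply(sub, 2, max) + 1e-9))
  }
})

test_that("composites are invariant to component order and weight rescaling", {
  foods <- shared_food_table()
  set.seed(123)
  for (i in 1:40) {
    spec <- random_spec(foods, 4, stats::runif(4, 0.5, 50))
    perm <- spec
    o <- sample(4)
    perm$components <- perm$components[o, ]
    scaled <- spec
    scaled$components$weight_percent <- spec$components$weight_percent * 7.3
    base <- profile_amounts(build_composite(spec, foods)$per_serving)
    expect_equal(profile_amounts(build_composite(perm, foods)$per_serving),
                 base, tolerance = 1e-12)
    expect_equal(profile_amounts(build_composite(scaled, foods)$per_serving),
                 base, tolerance = 1e-12)
  }
})

test_that("unknown food codes are reported by code", {
  foods <- shared_food_table()
  spec <- composite_spec("x", data.frame(food_code = "00000000",
                                         weight_percent = 1))
  expect_error(build_composite(spec, foods), "00000000")
  expect_error(food_profile(foods, "99999999"), "99999999")
})

test_that("published composites carry the printed per-serving values", {
  expect_equal(profile_amounts(reference_composite("A")$per_serving)[["sodium"]],
               399)
  expect_equal(
    profile_amounts(reference_composite("C")$per_serving)[["saturated_fat"]],
    5.7)
  expect_equal(
    profile_amounts(reference_composite("USDA2015")$per_serving)[["energy"]],
    77)
  expect_equal(profile_amounts(reference_composite("B")$per_serving)[["energy"]],
               127)
  # nutrients without printed composite rows are zero-filled
  expect_equal(profile_amounts(reference_composite("A")$per_serving)[["fiber"]],
               0)
  expect_error(reference_composite("D"))
  # the composite recipe records the published consumption shares
  expect_equal(sort(unname(reference_composite("A")$normalized_weights),
                    decreasing = TRUE)[1],
               47.76 / 99.99)
})

test_that("food tables round-trip through the CSV dialect", {
  foods <- shared_food_table()
  path <- tempfile(fileext = ".csv")
  write_food_table(foods, path)
  back <- read_food_table(path)
  cols <- paste0(nutrient_panel()$nutrient_id, "__", nutrient_panel()$unit)
  expect_equal(as.data.frame(back)[cols], as.data.frame(foods)[cols],
               tolerance = 1e-12)
  expect_identical(back$food_code, foods$food_code)

  # a table missing a panel column is refused, naming the nutrient
  broken <- as.data.frame(foods)
  broken[["sodium__mg"]] <- NULL
  write.csv(broken, path, row.names = FALSE)
  expect_error(read_food_table(path), "sodium__mg")
})
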