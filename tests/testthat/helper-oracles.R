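# shared helpers: independent brute-force oracles and random inputs

# element-wise weighted average computed with an explicit per-nutrient loop,
# independent of build_composite's vectorized path
naive_composite_amounts <- function(foods, spec) {
  panel <- nutrient_panel()
  w <- spec$components$weight_percent
  fr <- w / sum(w)
  out <- numeric(nrow(panel))
  names(out) <- panel$nutrient_id
  for (k in seq_along(panel$nutrient_id)) {
    col <- paste0(panel$nutrient_id[k], "__", panel$unit[k])
    acc <- 0
    for (j in seq_len(nrow(spec$components))) {
      i <- match(spec$components$food_code[j], foods$food_code)
      acc <- acc + fr[j] * foods[[col]][i]
    }
    out[k] <- acc
  }
  out
}

random_spec <- function(foods, n_components, weights) {
  codes <- sample(foods$food_code, n_components)
  composite_spec("random", data.frame(food_code = codes,
                                      weight_percent = weights))
}

random_profile <- function(basis = "per_serving") {
  panel <- nutrient_panel()
  nutrient_profile(stats::setNames(stats::runif(nrow(panel), 0, 100),
                                   panel$nutrient_id),
                   basis = basis)
}

# a medium synthetic food table shared across property tests
shared_food_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- generate_food_table(
      synthetic_config(seed = 424242L, n_foods_per_group = 5L))
    tab
  }
})
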