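#' The USDA 2000-kcal pattern day-level profile
#'
#' Day-level nutrient totals of the published USDA 2000-kcal Healthy
#' U.S.-Style Eating Pattern, as printed (2,003 kcal, 1,787 mg sodium, 3
#' cup-equivalents of dairy via the 2015 USDA dairy composite).
#'
#' @return A per-day [nutrient_profile()].
#' @export
usda_pattern_profile <- function() {
  tab <- read_fixture_csv("usda_pattern_2000.csv")
  nutrient_profile(stats::setNames(tab$amount, tab$nutrient_id),
                   basis = "per_day")
}

#' Define a reference eating pattern
#'
#' A reference pattern couples a day-level nutrient total with the dairy
#' component it already contains (a composite at a daily serving count),
#' so that the non-dairy remainder can be derived and other dairy
#' components substituted in. The default is the USDA 2000-kcal pattern
#' with 3 cup-equivalents of the 2015 USDA dairy composite.
#'
#' @param total per-day [nutrient_profile()] of the whole pattern.
#' @param dairy_component a `dairy_composite`.
#' @param dairy_servings daily cup-equivalents of that composite (> 0).
#' @param name pattern name.
#' @return A `reference_pattern`; construction fails if any nutrient's
#'   non-dairy remainder would be negative.
#' @export
reference_pattern <- function(total = usda_pattern_profile(),
                              dairy_component = reference_composite("USDA2015"),
                              dairy_servings = 3,
                              name = "USDA 2000-kcal pattern") {
  stopifnot(inherits(total, "nutrient_profile"),
            inherits(dairy_component, "dairy_composite"))
  if (!is.numeric(dairy_servings) || length(dairy_servings) != 1L ||
      dairy_servings <= 0)
    stop_df("dairy_servings must be a single positive number")
  ref <- structure(list(name = name, total = total,
                        dairy_component = dairy_component,
                        dairy_servings = dairy_servings),
                   class = "reference_pattern")
  derive_remainder(ref)  # validates non-negativity
  ref
}

#' Non-dairy remainder of a reference pattern
#'
#' Subtracts the pattern's dairy contribution (servings times the dairy
#' composite's per-serving profile) from the day-level total. A negative
#' remainder for any nutrient means the inputs are inconsistent and is an
#' error naming the nutrient.
#'
#' @param ref a [reference_pattern()].
#' @return Per-day [nutrient_profile()] of everything except dairy.
#' @examples
#' r <- derive_remainder(reference_pattern())
#' profile_amounts(r)[["sodium"]]  # 1787 - 3*202 = 1181
#' @export
derive_remainder <- function(ref) {
  stopifnot(inherits(ref, "reference_pattern"))
  dairy <- ref$dairy_servings * ref$dairy_component$per_serving$amounts
  rem <- ref$total$amounts - dairy
  rem[abs(rem) < 1e-9] <- 0
  if (any(rem < 0)) {
    bad <- names(rem)[which(rem < 0)[1]]
    stop_df("negative non-dairy remainder for %s (%g): pattern total and dairy component are inconsistent",
            bad, rem[[bad]])
  }
  new_profile_unchecked(rem, "per_day", ref$total$panel)
}

#' Define a serving-substitution plan
#'
#' A plan lists the dairy components (composites or single foods, via
#' their per-serving profiles) that replace the reference pattern's dairy
#' servings, with a serving count per component. The counts must sum to
#' the pattern's dairy serving total (3 cup-equivalents in the shipped
#' pattern) — the substitution swaps dairy for dairy and leaves the rest
#' of the pattern unchanged.
#'
#' @param name plan name (e.g. `"model2"`).
#' @param components list of `list(component =, servings =)` where
#'   `component` is a `dairy_composite` or a per-serving
#'   [nutrient_profile()], and `servings` a non-negative number.
#' @return A `substitution_plan`.
#' @export
substitution_plan <- function(name, components) {
  if (!length(components)) stop_df("plan '%s' has no components", name)
  components <- lapply(components, function(x) {
    pr <- x$component
    label <- x$label %||% if (inherits(pr, "dairy_composite")) pr$name else "food"
    if (inherits(pr, "dairy_composite")) pr <- pr$per_serving
    if (!inherits(pr, "nutrient_profile") || pr$basis != "per_serving")
      stop_df("plan '%s': each component must be a composite or per-serving profile",
              name)
    if (!is.numeric(x$servings) || length(x$servings) != 1L || x$servings < 0)
      stop_df("plan '%s': servings must be a single non-negative number", name)
    list(label = label, profile = pr, servings = as.numeric(x$servings))
  })
  structure(list(name = name, components = components),
            class = "substitution_plan")
}

plan_servings <- function(plan) sum(vapply(plan$components, `[[`, 0, "servings"))

#' Apply a substitution plan to a non-dairy remainder
#'
#' Computes the modeled day-level total: remainder plus the
#' serving-weighted sum of the plan's component profiles. Errors if the
#' plan's servings do not sum to the dairy serving total being replaced.
#'
#' @param remainder per-day [nutrient_profile()] from [derive_remainder()].
#' @param plan a [substitution_plan()].
#' @param dairy_servings serving total the plan must supply (default 3).
#' @return A `pattern_model` with `name`, `plan`, `remainder` and `total`.
#' @export
apply_plan <- function(remainder, plan, dairy_servings = 3) {
  stopifnot(inherits(remainder, "nutrient_profile"),
            inherits(plan, "substitution_plan"))
  if (remainder$basis != "per_day")
    stop_df("remainder must be a per-day profile")
  s <- plan_servings(plan)
  if (abs(s - dairy_servings) > 1e-9)
    stop_df("plan '%s' servings sum to %g, expected %g", plan$name, s,
            dairy_servings)
  total <- remainder
  for (cmp in plan$components) {
    contrib <- profile_with_basis(profile_scale(cmp$profile, cmp$servings),
                                  "per_day")
    total <- profile_add(total, contrib)
  }
  structure(list(name = plan$name, plan = plan, remainder = remainder,
                 total = total),
            class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  comp <- vapply(x$plan$components, function(c)
    sprintf("%g x %s", c$servings, c$label), "")
  cat(sprintf("<pattern_model> %s: %s\n", x$name, paste(comp, collapse = " + ")))
  a <- x$total$amounts
  cat(sprintf("  %g kcal, saturated fat %g g, sodium %g mg per day\n",
              a[["energy"]], a[["saturated_fat"]], a[["sodium"]]))
  invisible(x)
}

#' Model a pattern from a reference and a plan
#'
#' Convenience wrapper: derives the non-dairy remainder of `ref` and
#' applies `plan` at the reference's dairy serving count.
#'
#' @param ref a [reference_pattern()].
#' @param plan a [substitution_plan()].
#' @return A `pattern_model`.
#' @export
pattern_model <- function(ref, plan) {
  apply_plan(derive_remainder(ref), plan, ref$dairy_servings)
}

#' The shipped substitution plans
#'
#' The seven shipped plans replace the reference pattern's 3 dairy
#' cup-equivalents with: 3 servings of the updated fat-free composite A
#' (model 1, the comparison baseline); 2 of A plus 1 of the reduced-fat
#' composite B (model 2) or the whole-fat composite C (model 3); or 2 of A
#' plus 1 serving of a single food — whole milk, reduced-fat milk,
#' whole-fat cheese or reduced-fat cheese (models 4-7). The single-food
#' plans need per-cup profiles for those food codes, which the published
#' tables do not provide; pass a food table (e.g. a synthetic one) to get
#' them, otherwise only the composite-based plans are returned.
#'
#' @param foods optional `food_table` supplying food codes 11111000,
#'   11112110, 14410110, 14410120 for models 4-7.
#' @return Named list of [substitution_plan()]s.
#' @export
shipped_plans <- function(foods = NULL) {
  spec <- jsonlite::read_json(fixture_path("model_plans.json"))
  comps <- list(A = reference_composite("A"), B = reference_composite("B"),
                C = reference_composite("C"))
  out <- list()
  for (pl in spec$plans) {
    components <- list()
    ok <- TRUE
    for (cm in pl$components) {
      ref <- strsplit(cm$ref, ":", fixed = TRUE)[[1]]
      if (ref[1] == "composite") {
        components[[length(components) + 1L]] <-
          list(component = comps[[ref[2]]], servings = cm$servings)
      } else if (ref[1] == "food") {
        if (is.null(foods) ||
            !ref[2] %in% as_food_table(foods)$food_code) { ok <- FALSE; break }
        components[[length(components) + 1L]] <-
          list(component = food_profile(foods, ref[2]), servings = cm$servings,
               label = paste0("food ", ref[2]))
      } else stop_df("unknown component ref '%s'", cm$ref)
    }
    if (ok) out[[pl$name]] <- substitution_plan(pl$name, components)
  }
  out
}

#' Compute the shipped pattern models
#'
#' Runs [pattern_model()] for each requested shipped plan against the
#' USDA 2000-kcal reference pattern.
#'
#' @param models character vector of plan names (default: the three
#'   composite-based models).
#' @param foods optional `food_table` for the single-food models 4-7.
#' @return Named list of `pattern_model`s.
#' @examples
#' m <- reference_models("model1")
#' profile_amounts(m$model1$total)[["energy"]]  # 2006
#' @export
reference_models <- function(models = c("model1", "model2", "model3"),
                             foods = NULL) {
  plans <- shipped_plans(foods)
  missing <- setdiff(models, names(plans))
  if (length(missing))
    stop_df("plan(s) not available: %s (single-food plans need a food table)",
            paste(missing, collapse = ", "))
  ref <- reference_pattern()
  rem <- derive_remainder(ref)
  stats::setNames(lapply(models, function(m)
    apply_plan(rem, plans[[m]], ref$dairy_servings)), models)
}

#' Per-nutrient percent change between two models
#'
#' Percent change is computed on unrounded day-level totals,
#' `100 * (model - baseline) / baseline`, and displayed at one decimal.
#' Nutrients with a zero baseline are flagged `applicable = FALSE` and
#' reported as `NA` rather than computed.
#'
#' @param model,baseline `pattern_model`s on the same panel.
#' @return A `percent_change_report` data frame with `nutrient_id`,
#'   `baseline_amount`, `model_amount`, `pct_change` (unrounded),
#'   `display` (one decimal) and `applicable`.
#' @export
percent_change <- function(model, baseline) {
  stopifnot(inherits(model, "pattern_model"),
            inherits(baseline, "pattern_model"))
  if (!same_panel(model$total, baseline$total))
    stop_df("panel mismatch at nutrient '%s'",
            first_panel_difference(model$total, baseline$total))
  b <- baseline$total$amounts
  m <- model$total$amounts
  applicable <- b != 0
  pc <- ifelse(applicable, 100 * (m - b) / b, NA_real_)
  out <- data.frame(nutrient_id = names(b), baseline_amount = unname(b),
                    model_amount = unname(m), pct_change = unname(pc),
                    display = round_half_up(unname(pc), 1),
                    applicable = unname(applicable),
                    stringsAsFactors = FALSE)
  attr(out, "model") <- model$name
  attr(out, "baseline") <- baseline$name
  class(out) <- c("percent_change_report", "data.frame")
  out
}

#' Flag nutrient changes at labeling-claim scale
#'
#' U.S. nutrition labeling lets a food claim "good source" at 10% of the
#' Daily Value and "excellent source" at 20%; the same 10/20% cutoffs are
#' used here to call a percent change meaningful. Absolute changes of 20%
#' or more are tiered `excellent-source-scale`, 10 to <20%
#' `good-source-scale`; smaller changes are not flagged.
#'
#' @param report a [percent_change()] report.
#' @return Data frame of flagged rows: `nutrient_id`, `pct_change`, `tier`.
#' @export
flag_meaningful_changes <- function(report) {
  stopifnot(inherits(report, "percent_change_report"))
  pc <- report$pct_change
  tier <- ifelse(!is.na(pc) & abs(pc) >= 20, "excellent-source-scale",
                 ifelse(!is.na(pc) & abs(pc) >= 10, "good-source-scale", NA))
  keep <- !is.na(tier)
  data.frame(nutrient_id = report$nutrient_id[keep],
             pct_change = pc[keep], tier = tier[keep],
             stringsAsFactors = FALSE)
}
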