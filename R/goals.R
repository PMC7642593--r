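#' Dietary Reference Intake table for the sample age-sex groups
#'
#' Reference values for the two sample groups evaluated in the published
#' goal grid: females 19-30 years and males 51+ years. Each nutrient has
#' one goal per group — an RDA, an AI, a UL (sodium), or the 2000-kcal
#' energy goal. Values are standard DRI constants (the 2005-era potassium
#' AI of 4,700 mg, which is the only value consistent with the printed
#' grid, not the 2019 revision) and were cross-checked by back-computing
#' goal = amount / (percent/100) from matched printed cells.
#'
#' @return A `dri_table` data frame with columns `group`, `nutrient_id`,
#'   `goal_type` (`RDA`/`AI`/`UL`/`goal`), `value`, `unit`, `note`, and an
#'   `atwater` attribute `c(protein = 4, carbohydrate = 4, fat = 9)`
#'   kcal/g.
#' @export
dri_reference <- function() {
  if (!is.null(.dairyflex_cache$dri)) return(.dairyflex_cache$dri)
  d <- read_fixture_csv("dri_reference.csv")
  if (any(d$value <= 0)) stop_df("DRI goal values must be positive")
  dup <- duplicated(d[c("group", "nutrient_id")])
  if (any(dup))
    stop_df("duplicate DRI entry for %s/%s", d$group[dup][1],
            d$nutrient_id[dup][1])
  attr(d, "atwater") <- c(protein = 4, carbohydrate = 4, fat = 9)
  class(d) <- c("dri_table", "data.frame")
  .dairyflex_cache$dri <- d
  d
}

#' @rdname dri_reference
#' @param dri a `dri_table`.
#' @export
dri_groups <- function(dri = dri_reference()) unique(dri$group)

#' Percent of dietary goal per nutrient
#'
#' For each nutrient with a goal entry for the group, computes
#' `100 * amount / goal`, displayed as an integer (ties away from zero).
#' Panel nutrients without a goal entry (total and class fats, EPA/DHA,
#' stearic acid, cholesterol have none) are omitted with a warning of
#' class `dairyflex_no_goal_warning`.
#'
#' @param profile per-day [nutrient_profile()].
#' @param group group id, one of [dri_groups()].
#' @param dri a [dri_reference()] table.
#' @return Data frame `nutrient_id`, `amount`, `goal_type`, `goal`,
#'   `pct` (unrounded), `display` (integer).
#' @examples
#' m1 <- reference_models("model1")$model1
#' g <- suppressWarnings(pct_of_goal(m1$total, "females_19_30"))
#' g$display[g$nutrient_id == "calcium"]  # 149
#' @export
pct_of_goal <- function(profile, group, dri = dri_reference()) {
  stopifnot(inherits(profile, "nutrient_profile"))
  if (!group %in% dri$group)
    stop_df("unknown group '%s' (have: %s)", group,
            paste(dri_groups(dri), collapse = ", "))
  d <- dri[dri$group == group, ]
  i <- match(d$nutrient_id, names(profile$amounts))
  d <- d[!is.na(i), ]
  omitted <- setdiff(names(profile$amounts), d$nutrient_id)
  if (length(omitted))
    warn_df("dairyflex_no_goal_warning",
            "no %s goal entry for: %s", group, paste(omitted, collapse = ", "))
  amount <- profile$amounts[d$nutrient_id]
  pct <- 100 * amount / d$value
  data.frame(nutrient_id = d$nutrient_id, amount = unname(amount),
             goal_type = d$goal_type, goal = d$value, pct = unname(pct),
             display = round_half_up(unname(pct), 0),
             stringsAsFactors = FALSE)
}

#' Macronutrient percent of energy
#'
#' Percent of day-level calories from protein, carbohydrate and the fat
#' classes, using Atwater factors (4 kcal/g protein, 4 kcal/g
#' carbohydrate, 9 kcal/g for every fat class); alcohol is not modeled.
#' Energy is a panel entry, never recomputed from the macronutrients, and
#' must be positive.
#'
#' @param profile per-day [nutrient_profile()].
#' @param atwater named factors; defaults from [dri_reference()].
#' @return Data frame `nutrient_id`, `grams`, `kcal_per_g`, `pct`
#'   (unrounded), `display` (integer).
#' @export
pct_kcal <- function(profile, atwater = attr(dri_reference(), "atwater")) {
  stopifnot(inherits(profile, "nutrient_profile"))
  energy <- profile$amounts[["energy"]]
  if (energy <= 0) stop_df("energy must be positive to compute %% of kcal")
  rows <- c(protein = "protein", carbohydrate = "carbohydrate",
            total_fat = "fat", saturated_fat = "fat",
            monounsaturated_fat = "fat", polyunsaturated_fat = "fat")
  grams <- profile$amounts[names(rows)]
  f <- unname(atwater[rows])
  pct <- 100 * grams * f / energy
  data.frame(nutrient_id = names(rows), grams = unname(grams),
             kcal_per_g = f, pct = unname(pct),
             display = round_half_up(unname(pct), 0),
             stringsAsFactors = FALSE)
}

#' Saturated-fat and sodium screening thresholds
#'
#' The two headline limits the modeling is screened against: saturated
#' fat at no more than 10% of daily calories, and the 2,300 mg/d Chronic
#' Disease Risk Reduction (CDRR) intake level for sodium. The current
#' mean U.S. sodium intake (3,410 mg/d) is carried as report-only context
#' for the margin below current consumption.
#'
#' @param saturated_fat_max_pct_kcal limit on saturated fat, % of kcal.
#' @param sodium_cdrr_mg sodium CDRR, mg/day.
#' @param current_mean_sodium_mg report-only context value, mg/day.
#' @return A `threshold_set` list.
#' @export
threshold_set <- function(saturated_fat_max_pct_kcal = 10,
                          sodium_cdrr_mg = 2300,
                          current_mean_sodium_mg = 3410) {
  structure(list(saturated_fat_max_pct_kcal = saturated_fat_max_pct_kcal,
                 sodium_cdrr_mg = sodium_cdrr_mg,
                 current_mean_sodium_mg = current_mean_sodium_mg),
            class = "threshold_set")
}

#' Screen a day-level profile against the thresholds
#'
#' The saturated-fat judgment uses the integer display value of % kcal: a
#' pattern displaying 10 is at the limit, not exceeding it ("no more than
#' 10% of calories"). The sodium flag is `amount > CDRR`, so exactly
#' 2,300 mg does not exceed.
#'
#' @param profile per-day [nutrient_profile()].
#' @param thresholds a [threshold_set()].
#' @return A `threshold_report` list: `saturated_fat_pct_kcal` (unrounded),
#'   `saturated_fat_display`, `saturated_fat_within_limit`, `sodium_mg`,
#'   `sodium_exceeds_cdrr`, `sodium_below_current_mean_by_mg`.
#' @export
check_thresholds <- function(profile, thresholds = threshold_set()) {
  stopifnot(inherits(profile, "nutrient_profile"),
            inherits(thresholds, "threshold_set"))
  k <- pct_kcal(profile)
  sf <- k[k$nutrient_id == "saturated_fat", ]
  sodium <- profile$amounts[["sodium"]]
  structure(list(
    saturated_fat_pct_kcal = sf$pct,
    saturated_fat_display = sf$display,
    saturated_fat_within_limit =
      sf$display <= thresholds$saturated_fat_max_pct_kcal,
    sodium_mg = sodium,
    sodium_exceeds_cdrr = sodium > thresholds$sodium_cdrr_mg,
    sodium_below_current_mean_by_mg =
      thresholds$current_mean_sodium_mg - sodium),
    class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> saturated fat %d%% of kcal (%s limit); sodium %g mg (%s CDRR)\n",
              x$saturated_fat_display,
              if (x$saturated_fat_within_limit) "within" else "exceeds",
              x$sodium_mg,
              if (x$sodium_exceeds_cdrr) "exceeds" else "within"))
  invisible(x)
}

#' Full goal report for a model
#'
#' Combines [pct_of_goal()] for each group with the group-independent
#' [pct_kcal()] rows, mirroring the layout of the published goal grid.
#'
#' @param model a `pattern_model` (or per-day profile).
#' @param groups group ids (default: all in the DRI table).
#' @param dri a [dri_reference()] table.
#' @return Data frame `group`, `nutrient_id`, `metric`
#'   (`pct_rda`/`pct_ai`/`pct_ul`/`pct_goal`/`pct_kcal`), `amount`,
#'   `goal`, `pct`, `display`.
#' @export
goal_report <- function(model, groups = dri_groups(dri), dri = dri_reference()) {
  profile <- if (inherits(model, "pattern_model")) model$total else model
  stopifnot(inherits(profile, "nutrient_profile"))
  metric_of <- c(RDA = "pct_rda", AI = "pct_ai", UL = "pct_ul",
                 goal = "pct_goal")
  kc <- pct_kcal(profile)
  out <- do.call(rbind, lapply(groups, function(g) {
    pg <- withCallingHandlers(pct_of_goal(profile, g, dri),
      dairyflex_no_goal_warning = function(w) invokeRestart("muffleWarning"))
    rbind(
      data.frame(group = g, nutrient_id = pg$nutrient_id,
                 metric = unname(metric_of[pg$goal_type]),
                 amount = pg$amount, goal = pg$goal, pct = pg$pct,
                 display = pg$display, stringsAsFactors = FALSE),
      data.frame(group = g, nutrient_id = kc$nutrient_id,
                 metric = "pct_kcal", amount = kc$grams, goal = NA_real_,
                 pct = kc$pct, display = kc$display,
                 stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}
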