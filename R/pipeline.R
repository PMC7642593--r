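#' Configure a pipeline run
#'
#' Bundles everything [run_pipeline()] needs: which models to run, the
#' baseline for percent change, the DRI groups to evaluate, an optional
#' food table for the single-food models, and the output directory and
#' formats.
#'
#' @param out_dir output directory (created if absent).
#' @param models plan names; default the three composite-based models.
#' @param baseline baseline plan name for percent change.
#' @param groups DRI group ids.
#' @param food_table optional path to a food-table CSV, or a `food_table`.
#' @param formats subset of `c("csv", "json")`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       models = c("model1", "model2", "model3"),
                       baseline = "model1",
                       groups = dri_groups(),
                       food_table = NULL,
                       formats = c("csv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  structure(list(out_dir = out_dir, models = unique(c(baseline, models)),
                 baseline = baseline, groups = groups,
                 food_table = food_table, formats = formats),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Report-only: checks the food table (if any) for panel coverage, the
#' shipped plans for the serving-sum rule and positive weights, DRI
#' coverage for the requested groups, and that the baseline names a
#' defined plan. All violations are listed, not just the first.
#'
#' @param config a [run_config()].
#' @return Data frame `stage`, `message`; zero rows when well formed.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bad <- list()
  note <- function(stage, msg)
    bad[[length(bad) + 1L]] <<- data.frame(stage = stage, message = msg,
                                           stringsAsFactors = FALSE)
  panel <- nutrient_panel()
  foods <- NULL
  if (!is.null(config$food_table)) {
    if (is.character(config$food_table) && !file.exists(config$food_table)) {
      note("food_table", sprintf("file not found: %s", config$food_table))
    } else {
      foods <- tryCatch(
        if (is.character(config$food_table))
          read_food_table(config$food_table, panel)
        else as_food_table(config$food_table, panel),
        error = function(e) { note("food_table", conditionMessage(e)); NULL })
    }
  }
  plans <- tryCatch(shipped_plans(foods), error = function(e) {
    note("plans", conditionMessage(e)); list() })
  for (m in config$models) {
    if (!m %in% names(plans)) {
      note("plans", sprintf(
        "plan '%s' not available (single-food plans need a food table)", m))
      next
    }
    s <- plan_servings(plans[[m]])
    if (abs(s - 3) > 1e-9)
      note("plans", sprintf("plan '%s' servings sum to %g, expected 3", m, s))
  }
  if (!config$baseline %in% config$models)
    note("baseline", sprintf("baseline '%s' is not among the models",
                             config$baseline))
  dri <- dri_reference()
  for (g in config$groups) {
    if (!g %in% dri$group) {
      note("dri", sprintf("group '%s' not in the DRI table", g))
    } else if (any(dri$value[dri$group == g] <= 0)) {
      note("dri", sprintf("non-positive goal value for group '%s'", g))
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(stage = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Run the full modeling pipeline
#'
#' Chains the stages: load the reference pattern and composites, derive
#' the non-dairy remainder, apply each requested substitution plan,
#' compute percent change against the baseline, evaluate DRI goals for
#' each group, and screen the saturated-fat and sodium thresholds. Writes
#' a model-totals table, a percent-change table, a goal table and a
#' threshold summary to `out_dir` (CSV and/or a single JSON report with
#' the unrounded values and input checksums). Outputs are a deterministic
#' function of the inputs: re-running a config reproduces identical
#' files.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `models`, `percent_change`, `goals`,
#'   `thresholds` and `files` (paths written). Validation failures are an
#'   error listing every violation.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  problems <- validate_inputs(config)
  if (nrow(problems))
    stop_df("invalid configuration:\n%s",
            paste(sprintf("- [%s] %s", problems$stage, problems$message),
                  collapse = "\n"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  foods <- if (is.null(config$food_table)) NULL
    else if (is.character(config$food_table)) read_food_table(config$food_table)
    else config$food_table
  panel <- nutrient_panel()
  mods <- reference_models(config$models, foods)
  base <- mods[[config$baseline]]

  totals <- data.frame(nutrient_id = panel$nutrient_id, unit = panel$unit,
                       usda_pattern = usda_pattern_profile()$amounts,
                       stringsAsFactors = FALSE)
  pc_long <- NULL
  for (m in config$models) {
    totals[[m]] <- unname(mods[[m]]$total$amounts)
    totals[[paste0(m, "_display")]] <-
      round_for_display(mods[[m]]$total)$display
    rep_ <- percent_change(mods[[m]], base)
    rep_$model <- m
    pc_long <- rbind(pc_long, as.data.frame(rep_))
  }
  goals <- do.call(rbind, lapply(config$models, function(m)
    cbind(model = m, goal_report(mods[[m]], groups = config$groups))))
  thr <- do.call(rbind, lapply(config$models, function(m) {
    t <- check_thresholds(mods[[m]]$total)
    data.frame(model = m,
               saturated_fat_pct_kcal = t$saturated_fat_pct_kcal,
               saturated_fat_display = t$saturated_fat_display,
               saturated_fat_within_limit = t$saturated_fat_within_limit,
               sodium_mg = t$sodium_mg,
               sodium_exceeds_cdrr = t$sodium_exceeds_cdrr,
               sodium_below_current_mean_by_mg =
                 t$sodium_below_current_mean_by_mg,
               stringsAsFactors = FALSE)
  }))
  rownames(totals) <- rownames(pc_long) <- rownames(goals) <- rownames(thr) <- NULL

  files <- character()
  if ("csv" %in% config$formats) {
    paths <- file.path(config$out_dir,
                       c("model_totals.csv", "percent_change.csv",
                         "goal_report.csv", "thresholds.csv"))
    utils::write.csv(totals, paths[1], row.names = FALSE)
    utils::write.csv(pc_long, paths[2], row.names = FALSE)
    utils::write.csv(goals, paths[3], row.names = FALSE)
    utils::write.csv(thr, paths[4], row.names = FALSE)
    files <- c(files, paths)
  }
  if ("json" %in% config$formats) {
    jp <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(list(
      schema_version = "1.0",
      tool = list(package = "dairyflex",
                  version = as.character(utils::packageVersion("dairyflex"))),
      fixture_md5 = as.list(fixture_md5),
      baseline = config$baseline,
      models_exceeding_sodium_cdrr = thr$model[thr$sodium_exceeds_cdrr],
      model_totals = totals, percent_change = pc_long,
      goal_report = goals, thresholds = thr),
      jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, jp)
  }
  invisible(list(models = mods, percent_change = pc_long, goals = goals,
                 thresholds = thr, files = files))
}
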