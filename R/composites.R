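#' Specify a consumption-weighted dairy composite
#'
#' A composite spec is a recipe: a list of foods (by 8-digit food code)
#' with strictly positive consumption weights, expressed as percentages of
#' dairy intake. Raw weights need not sum to exactly 100 — the published
#' milk/cheese/yogurt shares (47.76, 47.30, 4.93) sum to 99.99 — because
#' weights are normalized when the composite is built.
#'
#' @param name composite name.
#' @param components data frame with columns `food_code` (character) and
#'   `weight_percent` (positive numeric), or a list of
#'   `list(food_code =, weight_percent =)` entries.
#' @return A `composite_spec` object.
#' @examples
#' composite_spec("A", data.frame(
#'   food_code = c("11113000", "14410130", "11411300"),
#'   weight_percent = c(47.76, 47.30, 4.93)))
#' @export
composite_spec <- function(name, components) {
  if (is.list(components) && !is.data.frame(components))
    components <- do.call(rbind, lapply(components, function(x)
      data.frame(food_code = as.character(x$food_code),
                 weight_percent = as.numeric(x$weight_percent))))
  if (!is.data.frame(components) ||
      !all(c("food_code", "weight_percent") %in% names(components)))
    stop_df("components must have food_code and weight_percent")
  if (nrow(components) == 0L)
    stop_df("composite spec '%s' has no components", name)
  if (any(!is.finite(components$weight_percent) |
            components$weight_percent <= 0))
    stop_df("composite spec '%s': weights must be strictly positive", name)
  if (anyDuplicated(components$food_code))
    stop_df("composite spec '%s': duplicated food_code %s", name,
            components$food_code[duplicated(components$food_code)][1])
  components$food_code <- as.character(components$food_code)
  structure(list(name = name,
                 components = components[c("food_code", "weight_percent")]),
            class = "composite_spec")
}

#' Normalize composite weights to fractions
#'
#' Divides each weight by the sum of all weights so the fractions total
#' exactly 1 (the published shares are "normalized to total 100%"). The
#' result is invariant to rescaling all raw weights by a constant.
#'
#' @param spec a [composite_spec()].
#' @return Named numeric vector (food_code to fraction) summing to 1.
#' @export
normalize_weights <- function(spec) {
  stopifnot(inherits(spec, "composite_spec"))
  w <- spec$components$weight_percent
  stats::setNames(w / sum(w), spec$components$food_code)
}

#' Build a composite from a food table
#'
#' The composite's per-serving profile is the weighted average of its
#' component foods' per-cup-equivalent profiles, with weights normalized
#' to fractions. Every nutrient amount therefore lies within the range of
#' the component foods' amounts (convexity), and component order is
#' irrelevant.
#'
#' @param spec a [composite_spec()].
#' @param foods a food table ([read_food_table()] or
#'   [generate_food_table()]).
#' @return A `dairy_composite` with `name`, `spec`, `normalized_weights`
#'   and `per_serving` (a per-serving [nutrient_profile()]).
#' @export
build_composite <- function(spec, foods) {
  stopifnot(inherits(spec, "composite_spec"))
  foods <- as_food_table(foods)
  missing <- setdiff(spec$components$food_code, foods$food_code)
  if (length(missing))
    stop_df("food_code %s not present in the food table", missing[1])
  fr <- normalize_weights(spec)
  total <- NULL
  for (code in names(fr)) {
    contrib <- profile_scale(food_profile(foods, code), fr[[code]])
    total <- if (is.null(total)) contrib else profile_add(total, contrib)
  }
  structure(list(name = spec$name, spec = spec, normalized_weights = fr,
                 per_serving = total),
            class = "dairy_composite")
}

#' @export
print.dairy_composite <- function(x, ...) {
  cat(sprintf("<dairy_composite> %s: %d component(s)\n",
              x$name, length(x$normalized_weights)))
  cat(sprintf("  energy %g kcal, saturated fat %g g, sodium %g mg per serving\n",
              x$per_serving$amounts[["energy"]],
              x$per_serving$amounts[["saturated_fat"]],
              x$per_serving$amounts[["sodium"]]))
  invisible(x)
}

#' Published per-serving dairy composites
#'
#' Returns one of the four published composites verbatim from the shipped
#' reference table: the 2015 USDA dairy food composite used in the
#' reference eating pattern, or the updated fat-free (A), reduced-fat (B)
#' and whole-fat (C) milk/cheese/yogurt composites. Per-serving values are
#' taken as printed, not rebuilt from individual food profiles (which were
#' not published); nutrients without a printed composite row are zero.
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"USDA2015"`.
#' @return A `dairy_composite`.
#' @examples
#' reference_composite("A")$per_serving$amounts[["sodium"]]  # 399
#' @export
reference_composite <- function(name = c("A", "B", "C", "USDA2015")) {
  name <- match.arg(name)
  key <- paste0("refcomp_", name)
  if (!is.null(.dairyflex_cache[[key]])) return(.dairyflex_cache[[key]])
  tab <- read_fixture_csv("dairy_composites.csv")
  col <- switch(name, USDA2015 = "usda_2015", A = "composite_a",
                B = "composite_b", C = "composite_c")
  amounts <- stats::setNames(tab[[col]], tab$nutrient_id)
  per_serving <- withCallingHandlers(
    nutrient_profile(amounts, basis = "per_serving", fill_missing = "zero"),
    dairyflex_fill_warning = function(w) invokeRestart("muffleWarning"))
  spec <- reference_composite_spec(name)
  res <- structure(list(name = name, spec = spec,
                        normalized_weights =
                          if (!is.null(spec)) normalize_weights(spec),
                        per_serving = per_serving),
                   class = "dairy_composite")
  .dairyflex_cache[[key]] <- res
  res
}

# shares and food codes behind the published composites; the 2015 USDA
# composite is represented only through its printed aggregate column (its
# component list, including a 1.5% soymilk share, has no published codes
# usable here), so its spec is NULL
reference_composite_spec <- function(name) {
  if (name == "USDA2015") return(NULL)
  codes <- read_fixture_csv("composite_food_codes.csv")
  shares <- read_fixture_csv("dairy_consumption_shares.csv")
  shares <- shares[shares$era == "2013-2016", ]
  codes <- codes[codes$composite == name, ]
  composite_spec(name, data.frame(
    food_code = codes$food_code[match(shares$component, codes$group)],
    weight_percent = shares$share_pct))
}

# ---- food tables ------------------------------------------------------

food_table_meta_cols <- c("food_code", "description", "group", "fat_tier")
food_groups <- c("milk", "cheese", "yogurt", "other")
fat_tiers <- c("fat_free", "low_fat", "reduced_fat", "whole")

nutrient_col_names <- function(panel) paste0(panel$nutrient_id, "__", panel$unit)

as_food_table <- function(x, panel = nutrient_panel()) {
  if (inherits(x, "food_table")) return(x)
  validate_food_table(x, panel)
}

validate_food_table <- function(df, panel = nutrient_panel()) {
  need <- c(food_table_meta_cols, nutrient_col_names(panel))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_df("food table missing column(s): %s", paste(missing, collapse = ", "))
  df$food_code <- as.character(df$food_code)
  if (anyDuplicated(df$food_code))
    stop_df("duplicated food_code %s", df$food_code[duplicated(df$food_code)][1])
  nut <- as.matrix(df[nutrient_col_names(panel)])
  if (nrow(df) && (any(!is.finite(nut)) || any(nut < 0)))
    stop_df("food table nutrient amounts must be finite and non-negative")
  attr(df, "panel") <- panel
  class(df) <- unique(c("food_table", class(df)))
  df
}

#' Read or write the per-food nutrient CSV dialect
#'
#' Food tables are CSVs with columns `food_code`, `description`, `group`
#' (milk/cheese/yogurt/other), `fat_tier` (fat_free/low_fat/reduced_fat/
#' whole), then one column per panel nutrient named `<nutrient_id>__<unit>`.
#' Amounts are per cup-equivalent.
#'
#' @param path file path.
#' @param panel a [nutrient_panel()].
#' @return `read_food_table()` returns a validated `food_table` data
#'   frame; `write_food_table()` returns `path` invisibly.
#' @export
read_food_table <- function(path, panel = nutrient_panel()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(food_code = "character"))
  validate_food_table(df, panel)
}

#' @rdname read_food_table
#' @param foods a `food_table`.
#' @export
write_food_table <- function(foods, path) {
  foods <- as_food_table(foods)
  utils::write.csv(as.data.frame(foods), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-serving profile of one food
#'
#' @param foods a `food_table`.
#' @param food_code 8-digit food code (character).
#' @return A per-serving [nutrient_profile()] (one cup-equivalent).
#' @export
food_profile <- function(foods, food_code) {
  foods <- as_food_table(foods)
  panel <- attr(foods, "panel")
  i <- match(as.character(food_code), foods$food_code)
  if (is.na(i))
    stop_df("food_code %s not present in the food table", food_code)
  amounts <- stats::setNames(
    as.numeric(foods[i, nutrient_col_names(panel)]), panel$nutrient_id)
  nutrient_profile(amounts, basis = "per_serving", panel = panel)
}
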