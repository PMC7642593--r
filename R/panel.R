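#' The fixed 34-nutrient panel
#'
#' Every profile in a run is defined over the same ordered nutrient panel:
#' 14 macronutrient rows (energy through cholesterol, including the
#' fatty-acid subclasses and fiber), 9 minerals and 11 vitamins. Units are
#' stored as printed in the source reference tables, even where the printed
#' header is unconventional (selenium, vitamin B-12 and vitamin K are
#' printed in mg although the magnitudes are conventionally micrograms);
#' amounts are treated as opaque quantities in those units and never
#' auto-converted. A `unit_note` column records each such case.
#'
#' Two logical columns drive the reproduction machinery:
#' `in_composite_table` marks the 24 nutrients with printed per-serving
#' composite values, and `reconstructible` additionally includes fiber
#' (dairy contributes none, so its composite value is exactly zero).
#' Nutrients that are neither (fatty-acid subclasses, iron, copper,
#' EPA/DHA) cannot be recomputed from printed inputs.
#'
#' @return A `nutrient_panel` data frame with columns `nutrient_id`,
#'   `label`, `unit`, `display_precision`, `category`,
#'   `in_composite_table`, `reconstructible`, `unit_note`.
#' @export
nutrient_panel <- function() {
  if (!is.null(.dairyflex_cache$panel)) return(.dairyflex_cache$panel)
  p <- read_fixture_csv("nutrient_panel.csv")
  validate_panel(p)
  class(p) <- c("nutrient_panel", "data.frame")
  .dairyflex_cache$panel <- p
  p
}

panel_units <- c("kcal", "g", "mg", "ug", "ug_RAE", "mg_AT", "IU")

validate_panel <- function(p) {
  if (anyDuplicated(p$nutrient_id))
    stop_df("duplicate nutrient_id in panel: %s",
            p$nutrient_id[duplicated(p$nutrient_id)][1])
  bad <- setdiff(unique(p$unit), panel_units)
  if (length(bad))
    stop_df("panel unit not in allowed vocabulary: %s", bad[1])
  if (nrow(p) != 34L)
    stop_df("panel must have 34 nutrients, got %d", nrow(p))
  if (any(p$display_precision < 0))
    stop_df("display_precision must be >= 0")
  invisible(p)
}

same_panel <- function(a, b) {
  identical(a$panel$nutrient_id, b$panel$nutrient_id) &&
    identical(a$panel$unit, b$panel$unit)
}

first_panel_difference <- function(a, b) {
  pa <- a$panel; pb <- b$panel
  n <- min(nrow(pa), nrow(pb))
  i <- which(pa$nutrient_id[seq_len(n)] != pb$nutrient_id[seq_len(n)] |
               pa$unit[seq_len(n)] != pb$unit[seq_len(n)])
  if (length(i)) pa$nutrient_id[i[1]] else pa$nutrient_id[n + 1] %||% "panel length"
}

#' Create a nutrient profile
#'
#' A nutrient profile is a complete vector of amounts over the fixed panel,
#' either per serving (one cup-equivalent for dairy components) or per day
#' (an eating-pattern total or remainder). Amounts must be non-negative:
#' a negative per-day remainder signals inconsistent inputs and is an
#' error, not a value to propagate.
#'
#' Missing panel nutrients are an error by default. With
#' `fill_missing = "zero"` they are filled with 0 and a warning of class
#' `dairyflex_fill_warning` lists them; this is the documented policy for
#' the dairy composite tables, which omit nutrients dairy does not supply
#' (fiber) alongside nutrients whose composite values were simply not
#' printed.
#'
#' @param amounts named numeric vector; names are panel `nutrient_id`s.
#' @param basis `"per_serving"` or `"per_day"`.
#' @param panel a [nutrient_panel()].
#' @param fill_missing `"error"` (default) or `"zero"`.
#' @return A `nutrient_profile` object.
#' @examples
#' p <- nutrient_profile(c(energy = 77, sodium = 202), fill_missing = "zero")
#' @export
nutrient_profile <- function(amounts, basis = c("per_serving", "per_day"),
                             panel = nutrient_panel(),
                             fill_missing = c("error", "zero")) {
  basis <- match.arg(basis)
  fill_missing <- match.arg(fill_missing)
  if (!is.numeric(amounts) || is.null(names(amounts)))
    stop_df("amounts must be a named numeric vector")
  unknown <- setdiff(names(amounts), panel$nutrient_id)
  if (length(unknown))
    stop_df("unknown nutrient_id: %s", paste(unknown, collapse = ", "))
  if (anyDuplicated(names(amounts)))
    stop_df("duplicated nutrient_id in amounts: %s",
            names(amounts)[duplicated(names(amounts))][1])
  missing <- setdiff(panel$nutrient_id, names(amounts))
  if (length(missing)) {
    if (fill_missing == "error")
      stop_df("amounts missing for panel nutrients: %s",
              paste(missing, collapse = ", "))
    warn_df("dairyflex_fill_warning",
            "filling %d missing panel nutrient(s) with 0: %s",
            length(missing), paste(missing, collapse = ", "))
  }
  full <- stats::setNames(numeric(nrow(panel)), panel$nutrient_id)
  full[names(amounts)] <- as.numeric(amounts)
  if (any(is.na(full)))
    stop_df("amounts must not contain NA (%s)",
            names(full)[which(is.na(full))[1]])
  neg <- names(full)[full < 0]
  if (length(neg))
    stop_df("negative amount for %s (%g); %s profiles must be non-negative",
            neg[1], full[neg[1]], basis)
  structure(list(amounts = full, basis = basis, panel = panel),
            class = "nutrient_profile")
}

new_profile_unchecked <- function(amounts, basis, panel) {
  structure(list(amounts = amounts, basis = basis, panel = panel),
            class = "nutrient_profile")
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat(sprintf("<nutrient_profile> basis: %s, %d nutrients\n",
              x$basis, length(x$amounts)))
  key <- c("energy", "protein", "total_fat", "saturated_fat", "sodium", "calcium")
  u <- x$panel$unit[match(key, x$panel$nutrient_id)]
  cat(paste(sprintf("  %s: %g %s", key, x$amounts[key], u), collapse = "\n"), "\n")
  invisible(x)
}

#' Extract profile amounts
#'
#' @param x a `nutrient_profile`.
#' @return Named numeric vector in panel order.
#' @export
profile_amounts <- function(x) {
  stopifnot(inherits(x, "nutrient_profile"))
  x$amounts
}

#' @rdname profile_amounts
#' @export
profile_basis <- function(x) {
  stopifnot(inherits(x, "nutrient_profile"))
  x$basis
}

#' Element-wise profile sum
#'
#' Adds two profiles on the same panel and basis. Value semantics: the
#' inputs are not modified. Adding a per-day remainder and scaled
#' per-serving components is the caller's job via [profile_scale()] and
#' [profile_with_basis()].
#'
#' @param a,b `nutrient_profile` objects on the same panel and basis.
#' @return A `nutrient_profile` with element-wise sums, panel order kept.
#' @export
profile_add <- function(a, b) {
  stopifnot(inherits(a, "nutrient_profile"), inherits(b, "nutrient_profile"))
  if (!same_panel(a, b))
    stop_df("panel mismatch at nutrient '%s'", first_panel_difference(a, b))
  if (!identical(a$basis, b$basis))
    stop_df("basis mismatch: %s vs %s", a$basis, b$basis)
  new_profile_unchecked(a$amounts + b$amounts, a$basis, a$panel)
}

#' Scale a profile by a non-negative factor
#'
#' @param a a `nutrient_profile`.
#' @param k single non-negative number (e.g. a serving count).
#' @return The element-wise multiple; same panel and basis.
#' @export
profile_scale <- function(a, k) {
  stopifnot(inherits(a, "nutrient_profile"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k))
    stop_df("k must be a single number")
  if (k < 0)
    stop_df("k must be >= 0, got %g", k)
  new_profile_unchecked(a$amounts * k, a$basis, a$panel)
}

#' Relabel a profile's basis
#'
#' Used when per-serving amounts scaled by a daily serving count become a
#' per-day contribution. Pure relabeling; amounts are untouched.
#'
#' @param a a `nutrient_profile`.
#' @param basis `"per_serving"` or `"per_day"`.
#' @return The profile with the new basis.
#' @export
profile_with_basis <- function(a, basis = c("per_serving", "per_day")) {
  stopifnot(inherits(a, "nutrient_profile"))
  basis <- match.arg(basis)
  new_profile_unchecked(a$amounts, basis, a$panel)
}

#' Round a profile for display
#'
#' Applies the per-nutrient display precision of the panel (energy and
#' minerals to integers, saturated fat to one decimal, EPA/DHA/stearic
#' acid to two, and so on) with half-away-from-zero ties. Report-time
#' only: no internal arithmetic ever uses these values.
#'
#' @param a a `nutrient_profile`.
#' @return Data frame with `nutrient_id`, `label`, `unit`, `amount`
#'   (unrounded) and `display` (rounded); rounding is idempotent.
#' @export
round_for_display <- function(a) {
  stopifnot(inherits(a, "nutrient_profile"))
  p <- a$panel
  data.frame(nutrient_id = p$nutrient_id, label = p$label, unit = p$unit,
             amount = unname(a$amounts),
             display = round_half_up(unname(a$amounts), p$display_precision),
             stringsAsFactors = FALSE)
}
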