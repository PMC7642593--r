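#' Configure the synthetic food-record generator
#'
#' The generator emulates the structure of FNDDS-like per-cup-equivalent
#' dairy records — milk, cheese and yogurt crossed with four fat tiers —
#' with nutrient magnitudes loosely calibrated to the published composite
#' table so that composites built from them are plausible. It exists so
#' that composite construction, substitution modeling and the single-food
#' plans are fully testable without any database download; synthetic
#' records are clearly non-authoritative and are never a source of
#' published-value comparisons.
#'
#' @param seed integer seed; identical seeds give identical output.
#' @param n_foods_per_group foods generated per (group, fat tier) cell.
#' @param sdlog log-scale noise of nutrient draws (log-normal; > 0
#'   nutrients only, zero-centered nutrients stay exactly zero).
#' @param consumption_concentration Dirichlet concentration of the
#'   consumption-share draws; large values give near-equal shares.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_foods_per_group = 3L,
                             sdlog = 0.15, consumption_concentration = 5) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_df("seed must be a single integer")
  if (!is.numeric(n_foods_per_group) || n_foods_per_group < 0)
    stop_df("n_foods_per_group must be a non-negative integer")
  if (!is.numeric(sdlog) || sdlog <= 0)
    stop_df("sdlog must be positive")
  if (!is.numeric(consumption_concentration) || consumption_concentration <= 0)
    stop_df("consumption_concentration must be positive")
  structure(list(seed = as.integer(seed),
                 n_foods_per_group = as.integer(n_foods_per_group),
                 sdlog = sdlog,
                 consumption_concentration = consumption_concentration),
            class = "synthetic_config")
}

# per-cup-equivalent nutrient centers by group, before fat-tier scaling.
# fat-linked nutrients are expressed through total fat via fixed fatty-acid
# fractions of dairy fat; the whole-tier fat center is strictly above the
# fat-free center by construction
synthetic_centers <- function(panel = nutrient_panel()) {
  base <- list(
    milk   = c(protein = 8.5, carbohydrate = 12, fiber = 0, cholesterol = 10,
               calcium = 300, iron = 0.1, magnesium = 27, phosphorus = 230,
               potassium = 360, sodium = 110, zinc = 1.0, copper = 0.02,
               selenium = 6, vitamin_a = 140, vitamin_e = 0.1,
               vitamin_d = 110, vitamin_c = 0.5, thiamin = 0.1,
               riboflavin = 0.4, niacin = 0.2, vitamin_b6 = 0.1,
               vitamin_b12 = 1.2, choline = 38, vitamin_k = 0.3),
    cheese = c(protein = 10, carbohydrate = 2.5, fiber = 0, cholesterol = 35,
               calcium = 300, iron = 0.2, magnesium = 12, phosphorus = 300,
               potassium = 60, sodium = 400, zinc = 1.5, copper = 0.02,
               selenium = 10, vitamin_a = 110, vitamin_e = 0.2,
               vitamin_d = 15, vitamin_c = 0, thiamin = 0.02,
               riboflavin = 0.2, niacin = 0.05, vitamin_b6 = 0.04,
               vitamin_b12 = 0.7, choline = 10, vitamin_k = 0.8),
    yogurt = c(protein = 9, carbohydrate = 15, fiber = 0, cholesterol = 12,
               calcium = 330, iron = 0.1, magnesium = 30, phosphorus = 260,
               potassium = 420, sodium = 130, zinc = 1.5, copper = 0.02,
               selenium = 8, vitamin_a = 70, vitamin_e = 0.1,
               vitamin_d = 40, vitamin_c = 1, thiamin = 0.1,
               riboflavin = 0.4, niacin = 0.2, vitamin_b6 = 0.1,
               vitamin_b12 = 1.0, choline = 35, vitamin_k = 0.3))
  fat_center <- list(milk = 8, cheese = 14, yogurt = 8)   # whole tier, g/cup-eq
  tier_scale <- c(fat_free = 0.05, low_fat = 0.3, reduced_fat = 0.6, whole = 1)
  fa_frac <- c(saturated_fat = 0.62, monounsaturated_fat = 0.28,
               polyunsaturated_fat = 0.05, linoleic_acid = 0.035,
               linolenic_acid = 0.01, stearic_acid = 0.12, epa = 0, dha = 0)
  out <- list()
  for (g in names(base)) for (tier in names(tier_scale)) {
    fat <- fat_center[[g]] * tier_scale[[tier]]
    amt <- stats::setNames(numeric(nrow(panel)), panel$nutrient_id)
    amt[names(base[[g]])] <- base[[g]]
    amt["total_fat"] <- fat
    amt[names(fa_frac)] <- fat * fa_frac
    # cholesterol tracks fat level too
    amt["cholesterol"] <- amt[["cholesterol"]] * (0.3 + 0.7 * tier_scale[[tier]])
    amt["energy"] <- 4 * (amt[["protein"]] + amt[["carbohydrate"]]) + 9 * fat
    out[[paste(g, tier, sep = ".")]] <- amt
  }
  out
}

#' Generate a synthetic FNDDS-like food table
#'
#' Draws `n_foods_per_group` per-cup-equivalent food records for every
#' (milk/cheese/yogurt, fat tier) cell. Positive nutrient centers get
#' independent log-normal noise (`meanlog = log(center)`, `sdlog` from the
#' config), so all amounts stay non-negative; structurally zero nutrients
#' (fiber, EPA/DHA in the shipped centers) stay zero. Output is
#' deterministic for a given seed; the seed is recorded in the `seed`
#' attribute. Food codes are synthetic 8-digit codes in the 90xxxxxx
#' range.
#'
#' In addition to the 90xxxxxx-coded records, one stand-in record is drawn
#' for each of the four single foods used by the shipped single-food
#' substitution plans (whole milk 11111000, reduced-fat milk 11112110,
#' whole-fat cheese 14410110, reduced-fat cheese 14410120), whose real
#' per-cup profiles were never published. They are synthetic and
#' non-authoritative — their descriptions say so — and exist only so the
#' single-food plans can be exercised. Set
#' `include_reference_codes = FALSE` to omit them; an empty configuration
#' (`n_foods_per_group = 0`) always yields an empty table.
#'
#' @param cfg a [synthetic_config()].
#' @param panel a [nutrient_panel()].
#' @param include_reference_codes also draw the four labeled stand-ins.
#' @return A `food_table` data frame.
#' @export
generate_food_table <- function(cfg, panel = nutrient_panel(),
                                include_reference_codes = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  centers <- synthetic_centers(panel)
  cells <- expand.grid(group = c("milk", "cheese", "yogurt"),
                       fat_tier = fat_tiers, stringsAsFactors = FALSE)
  draw_one <- function(center, code, description, g, tier) {
    amt <- center
    pos <- amt > 0
    amt[pos] <- stats::rlnorm(sum(pos), meanlog = log(amt[pos]),
                              sdlog = cfg$sdlog)
    df <- data.frame(food_code = code, description = description,
                     group = g, fat_tier = tier, stringsAsFactors = FALSE)
    df[nutrient_col_names(panel)] <- as.list(unname(amt))
    df
  }
  standins <- data.frame(
    food_code = c("11111000", "11112110", "14410110", "14410120"),
    group = c("milk", "milk", "cheese", "cheese"),
    fat_tier = c("whole", "reduced_fat", "whole", "reduced_fat"),
    stringsAsFactors = FALSE)
  rows <- withr::with_seed(cfg$seed, {
    main <- lapply(seq_len(nrow(cells)), function(i) {
      g <- cells$group[i]; tier <- cells$fat_tier[i]
      center <- centers[[paste(g, tier, sep = ".")]]
      if (cfg$n_foods_per_group == 0L) return(NULL)
      do.call(rbind, lapply(seq_len(cfg$n_foods_per_group), function(j)
        draw_one(center, sprintf("9%d%d%02d000", i %/% 10, i %% 10, j),
                 sprintf("synthetic %s, %s #%d", g, gsub("_", "-", tier), j),
                 g, tier)))
    })
    if (include_reference_codes && cfg$n_foods_per_group > 0L) {
      main <- c(main, lapply(seq_len(nrow(standins)), function(i) {
        g <- standins$group[i]; tier <- standins$fat_tier[i]
        draw_one(centers[[paste(g, tier, sep = ".")]], standins$food_code[i],
                 sprintf("SYNTHETIC non-authoritative stand-in for food code %s (%s, %s)",
                         standins$food_code[i], g, gsub("_", "-", tier)),
                 g, tier)
      }))
    }
    main
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(food_code = character(), description = character(),
                     group = character(), fat_tier = character(),
                     stringsAsFactors = FALSE)
    df[nutrient_col_names(panel)] <- lapply(nutrient_col_names(panel),
                                            function(x) numeric())
  }
  df <- validate_food_table(df, panel)
  attr(df, "seed") <- cfg$seed
  df
}

#' Draw a consumption-weighted composite spec from a food table
#'
#' Emulates the consumption-share weighting stage: picks one
#' representative food per group (milk, cheese, yogurt) present in the
#' table, preferring the requested fat tier, and draws positive shares
#' from a symmetric Dirichlet distribution scaled to total 100 (so raw
#' shares sum to ~100 before normalization, like the published 99.99).
#' Deterministic per the config seed (offset so the share draw differs
#' from the food draw).
#'
#' @param cfg a [synthetic_config()].
#' @param foods a non-empty `food_table`.
#' @param fat_tier preferred fat tier of the representatives.
#' @return A [composite_spec()].
#' @export
generate_consumption_shares <- function(cfg, foods, fat_tier = "fat_free") {
  stopifnot(inherits(cfg, "synthetic_config"))
  foods <- as_food_table(foods)
  if (!nrow(foods)) stop_df("food table is empty")
  reps <- vapply(c("milk", "cheese", "yogurt"), function(g) {
    cand <- foods[foods$group == g, ]
    if (!nrow(cand)) return(NA_character_)
    pref <- cand[cand$fat_tier == fat_tier, ]
    if (nrow(pref)) pref$food_code[1] else cand$food_code[1]
  }, "")
  reps <- reps[!is.na(reps)]
  if (!length(reps)) stop_df("no milk/cheese/yogurt records in the food table")
  shares <- withr::with_seed(cfg$seed + 1L, {
    g <- stats::rgamma(length(reps), shape = cfg$consumption_concentration)
    100 * g / sum(g)
  })
  composite_spec("synthetic composite",
                 data.frame(food_code = unname(reps),
                            weight_percent = shares))
}
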