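## DII reference parameters: the per-parameter global mean, global SD and
## overall inflammatory effect score that the index algebra consumes.

#' Dietary parameters available for DII scoring
#'
#' The 25 dietary parameters commonly available from a semi-quantitative FFQ
#' processed against a food-composition database, with the daily intake scale
#' used by the synthetic reference generator. The full literature DII catalog
#' has 45 parameters; the index is explicitly flexible in how many are used.
#'
#' @format A data.frame with columns `parameter`, `unit`, `typical_mean`.
#' @export
dii_parameters <- data.frame(
  parameter = c(
    "energy_kcal", "protein_g", "total_fat_g", "vitamin_b12_ug",
    "vitamin_b6_mg", "niacin_mg", "thiamin_mg", "riboflavin_mg",
    "folic_acid_ug", "vitamin_c_mg", "vitamin_d_ug", "fiber_g",
    "caffeine_g", "cholesterol_mg", "magnesium_mg", "vitamin_a_re",
    "vitamin_e_mg", "zinc_mg", "selenium_ug", "mufa_g", "pufa_g",
    "iron_mg", "beta_carotene_ug", "carbohydrate_g", "saturated_fat_g"),
  unit = c(
    "kcal/day", "g/day", "g/day", "ug/day", "mg/day", "mg/day", "mg/day",
    "mg/day", "ug/day", "mg/day", "ug/day", "g/day", "g/day", "mg/day",
    "mg/day", "RE/day", "mg/day", "mg/day", "ug/day", "g/day", "g/day",
    "mg/day", "ug/day", "g/day", "g/day"),
  typical_mean = c(
    2100, 80, 70, 5, 1.5, 26, 1.7, 1.7, 275, 115, 6, 18, 0.3, 280, 310,
    900, 9, 10, 67, 25, 15, 13, 3700, 270, 28),
  stringsAsFactors = FALSE
)

#' Generate a synthetic DII reference-parameter table
#'
#' The reference table holds, for every dietary parameter, the global mean and
#' global standard deviation of daily intake together with its overall
#' inflammatory effect score (positive = pro-inflammatory, negative =
#' anti-inflammatory, magnitude bounded by 1). The literature reference values
#' behind published DII scores are not redistributable here, so this generator
#' produces a clearly synthetic stand-in on realistic intake scales; any
#' user-supplied CSV with the same columns can be used instead throughout the
#' package.
#'
#' @param n_nutrients Number of dietary parameters (rows). When `<= 25` the
#'   parameter names and intake scales come from [dii_parameters]; beyond 25,
#'   synthetic names and log-normal scales are appended.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param anti_fraction Fraction of parameters given a negative
#'   (anti-inflammatory) effect score; exactly `round(anti_fraction *
#'   n_nutrients)` rows are negative.
#' @return A data.frame with columns `parameter`, `unit`, `global_mean`,
#'   `global_sd`, `effect_score`.
#' @examples
#' ref <- generate_reference_table(25, seed = 1)
#' stopifnot(all(ref$global_sd > 0), all(abs(ref$effect_score) <= 1))
#' @export
generate_reference_table <- function(n_nutrients, seed = 1L,
                                     anti_fraction = 0.45) {
  assert_that(is.numeric(n_nutrients) && length(n_nutrients) == 1 &&
                n_nutrients >= 1 && n_nutrients == round(n_nutrients),
              "n_nutrients must be a positive integer")
  assert_that(anti_fraction >= 0 && anti_fraction < 1,
              "anti_fraction must be in [0, 1)")
  n <- as.integer(n_nutrients)

  set.seed(derive_seed(seed, 11L))
  k <- min(n, nrow(dii_parameters))
  name <- dii_parameters$parameter[seq_len(k)]
  unit <- dii_parameters$unit[seq_len(k)]
  base <- dii_parameters$typical_mean[seq_len(k)]
  if (n > k) {
    extra <- seq.int(k + 1, n)
    name <- c(name, sprintf("parameter_%02d", extra))
    unit <- c(unit, rep("unit/day", length(extra)))
    base <- c(base, stats::rlnorm(length(extra), log(50), 1.5))
  }

  # Jitter the canonical scales slightly so distinct seeds give distinct
  # (but still plausible) reference worlds; CV of daily intake 0.2-0.5.
  global_mean <- base * stats::rlnorm(n, 0, 0.10)
  global_sd <- global_mean * stats::runif(n, 0.20, 0.50)

  n_neg <- round(anti_fraction * n)
  magnitude <- stats::runif(n, 0.02, 0.66)
  sign <- rep(1, n)
  if (n_neg > 0) sign[sample.int(n, n_neg)] <- -1

  data.frame(parameter = name, unit = unit,
             global_mean = global_mean, global_sd = global_sd,
             effect_score = sign * magnitude,
             stringsAsFactors = FALSE)
}

validate_reference <- function(reference) {
  need <- c("parameter", "global_mean", "global_sd", "effect_score")
  missing <- setdiff(need, names(reference))
  assert_that(length(missing) == 0,
              "reference table lacks column(s): %s",
              paste(missing, collapse = ", "))
  assert_that(!anyDuplicated(reference$parameter),
              "reference parameter names must be unique")
  assert_that(all(is.finite(reference$global_mean)),
              "reference global_mean must be finite")
  assert_that(all(is.finite(reference$global_sd) & reference$global_sd > 0),
              "reference global_sd must be positive")
  invisible(reference)
}
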