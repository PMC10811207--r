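## FFQ processing: frequency x portion to daily grams, daily grams x
## food-composition matrix to daily nutrient intakes, and the cohort's
## energy-based exclusion rule.

# Days per reporting period used to normalize FFQ frequencies.
period_days <- c(day = 1, week = 7, month = 30.44, year = 365.25)

#' Convert an FFQ frequency/portion pair to grams per day
#'
#' @param frequency Consumption events per reference period (>= 0).
#' @param period One of `"day"`, `"week"`, `"month"` (30.44 days), `"year"`
#'   (365.25 days); vectorized.
#' @param portion_grams Grams consumed per event (>= 0).
#' @return Grams per day: `frequency * portion_grams / days_in_period`.
#' @examples
#' daily_grams(7, "week", 100)    # 100 g/day
#' daily_grams(3, "month", 150)   # 3 * 150 / 30.44
#' @export
daily_grams <- function(frequency, period, portion_grams) {
  bad <- setdiff(unique(period), names(period_days))
  if (length(bad)) stopf("unknown frequency period(s): %s",
                         paste(bad, collapse = ", "))
  assert_that(all(frequency >= 0), "frequencies must be non-negative")
  assert_that(all(portion_grams >= 0), "portions must be non-negative")
  frequency * portion_grams / unname(period_days[period])
}

#' Pivot a long FFQ table to a participants-by-foods daily-grams matrix
#'
#' @param ffq data.frame with columns `participant_id`, `food_id`,
#'   `frequency`, `period`, `portion_grams`; one row per (participant, food).
#' @return data.frame: `participant_id` plus one grams/day column per food.
#' @export
ffq_daily_grams <- function(ffq) {
  need <- c("participant_id", "food_id", "frequency", "period", "portion_grams")
  missing <- setdiff(need, names(ffq))
  assert_that(length(missing) == 0, "ffq lacks column(s): %s",
              paste(missing, collapse = ", "))
  assert_that(!anyDuplicated(ffq[c("participant_id", "food_id")]),
              "duplicate (participant, food) pairs in FFQ")
  g <- daily_grams(ffq$frequency, ffq$period, ffq$portion_grams)
  ids <- unique(ffq$participant_id)
  foods <- unique(ffq$food_id)
  m <- matrix(0, length(ids), length(foods), dimnames = list(NULL, foods))
  m[cbind(match(ffq$participant_id, ids), match(ffq$food_id, foods))] <- g
  cbind(data.frame(participant_id = ids, stringsAsFactors = FALSE),
        as.data.frame(m, check.names = FALSE))
}

#' Daily nutrient intakes from daily grams and a composition matrix
#'
#' Nutrient intake is additive over foods: `(grams / 100) %*% composition`,
#' where the composition matrix holds each nutrient's amount per 100 g of
#' each food. A food reported in the grams table but absent from the
#' composition matrix is a hard error (silent dropping would bias the DII).
#'
#' @param grams data.frame from [ffq_daily_grams()] (`participant_id` +
#'   per-food grams/day columns), or a bare numeric matrix with food columns.
#' @param composition Foods-by-nutrients matrix (rownames = food ids) or a
#'   data.frame with a `food_id` column; entries are per-100 g amounts.
#' @return data.frame: `participant_id` plus one column per nutrient
#'   (daily intake in the composition's units).
#' @export
nutrient_intakes <- function(grams, composition) {
  comp <- composition
  if (is.data.frame(comp)) {
    assert_that("food_id" %in% names(comp),
                "composition data.frame needs a food_id column")
    rn <- comp$food_id
    comp <- as.matrix(comp[setdiff(names(comp), "food_id")])
    rownames(comp) <- rn
  }
  ids <- NULL
  if (is.data.frame(grams)) {
    assert_that("participant_id" %in% names(grams),
                "grams table needs a participant_id column")
    ids <- grams$participant_id
    grams <- as.matrix(grams[setdiff(names(grams), "participant_id")])
  }
  foods <- colnames(grams)
  assert_that(!is.null(foods), "grams matrix must have food column names")
  absent <- setdiff(foods, rownames(comp))
  if (length(absent)) stopf("food(s) missing from composition matrix: %s",
                            paste(absent, collapse = ", "))
  intake <- (grams / 100) %*% comp[foods, , drop = FALSE]
  out <- as.data.frame(intake, check.names = FALSE)
  if (!is.null(ids)) out <- cbind(data.frame(participant_id = ids,
                                             stringsAsFactors = FALSE), out)
  out
}

#' Energy-based exclusion rule
#'
#' Excludes participants whose daily energy intake lies more than 3 standard
#' deviations from the cohort mean. Mean and (sample, n-1) SD are computed
#' once over the full input; the rule is single-pass, not iterated. With zero
#' SD (all energies identical) nobody is excluded.
#'
#' @param intakes data.frame containing `participant_id` and an energy
#'   column.
#' @param energy_col Name of the energy column (default `"energy_kcal"`).
#' @param k Number of SDs (default 3).
#' @return List with `retained` (the filtered data.frame) and `excluded_ids`.
#' @export
energy_exclusion <- function(intakes, energy_col = "energy_kcal", k = 3) {
  assert_that(energy_col %in% names(intakes),
              "energy column '%s' not found", energy_col)
  assert_that(nrow(intakes) >= 2,
              "energy exclusion needs at least 2 participants")
  e <- intakes[[energy_col]]
  m <- mean(e)
  s <- stats::sd(e)
  out <- abs(e - m) > k * s
  list(retained = intakes[!out, , drop = FALSE],
       excluded_ids = intakes$participant_id[out],
       mean = m, sd = s)
}
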