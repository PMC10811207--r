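## Dietary Inflammatory Index engine.
##
## For each dietary parameter the daily intake is standardized against a
## global reference (Z-score), mapped to a centered percentile in [-1, 1],
## and weighted by the parameter's overall inflammatory effect score; the sum
## of the weighted scores over all parameters is the overall DII. Positive
## scores mark a pro-inflammatory diet, negative an anti-inflammatory one.

#' Standardize an intake against the global reference
#'
#' @param intake Daily intake (parameter units/day); vectorized.
#' @param mean,sd Global reference mean and standard deviation on the same
#'   scale; `sd` must be strictly positive.
#' @return `(intake - mean) / sd`.
#' @export
dii_z_score <- function(intake, mean, sd) {
  assert_that(all(is.finite(sd)) && all(sd > 0),
              "global sd must be strictly positive")
  (intake - mean) / sd
}

#' Centered percentile transform
#'
#' Maps a Z-score to a score in `[-1, 1]`: the percentile is doubled and
#' shifted down by one, so that the reference-mean intake scores 0. Two
#' percentile definitions are supported: `normal_cdf` uses the standard
#' normal distribution function (the original DII construction), `empirical`
#' uses within-cohort ranks, `(rank - 0.5) / n` with average ties, which
#' makes the cohort mean of each parameter's score exactly zero.
#'
#' @param z Numeric vector of Z-scores (for `empirical`, the whole cohort's
#'   vector for one parameter).
#' @param method `"normal_cdf"` (default) or `"empirical"`.
#' @return Centered percentiles in `[-1, 1]`.
#' @export
centered_percentile <- function(z, method = c("normal_cdf", "empirical")) {
  method <- match.arg(method)
  if (method == "normal_cdf") {
    assert_that(all(is.finite(z)), "z must be finite for normal_cdf")
    2 * stats::pnorm(z) - 1
  } else {
    n <- length(z)
    assert_that(n >= 2, "empirical percentiles need a cohort of size >= 2")
    p <- (rank(z, ties.method = "average") - 0.5) / n
    2 * p - 1
  }
}

#' Parameter-specific DII score
#'
#' @param centered_percentile Centered percentile in `[-1, 1]`.
#' @param effect_score Overall inflammatory effect score of the parameter.
#' @return Their product: the dietary parameter-specific DII score.
#' @export
parameter_score <- function(centered_percentile, effect_score) {
  assert_that(all(abs(centered_percentile) <= 1 + 1e-12),
              "centered percentiles must lie in [-1, 1]")
  centered_percentile * effect_score
}

#' Overall DII score
#'
#' @param parameter_scores Numeric vector (or matrix, participants in rows) of
#'   parameter-specific scores.
#' @return Row sums: the overall DII; bounded by the sum of absolute effect
#'   scores of the included parameters.
#' @export
overall_dii <- function(parameter_scores) {
  if (is.matrix(parameter_scores) || is.data.frame(parameter_scores)) {
    assert_that(ncol(parameter_scores) >= 1, "no parameter scores supplied")
    rowSums(as.matrix(parameter_scores))
  } else {
    assert_that(length(parameter_scores) >= 1, "no parameter scores supplied")
    sum(parameter_scores)
  }
}

#' Cohort-relative DII quartiles
#'
#' Rank-based assignment: participant with rank r (ties to the minimum rank)
#' gets quartile `ceiling(4 r / n)`, so values tied at a cut point fall in the
#' lower quartile and the assignment is deterministic.
#'
#' @param overall Numeric vector of overall DII scores, length >= 4.
#' @return Integer vector in 1..4.
#' @export
dii_quartiles <- function(overall) {
  n <- length(overall)
  assert_that(n >= 4, "quartiles need at least 4 participants")
  r <- rank(overall, ties.method = "min")
  as.integer(ceiling(4 * r / n))
}

#' Compute the DII for a cohort
#'
#' Applies the full chain (Z-score, centered percentile, effect-score
#' weighting, summation) to a participants-by-parameters intake table.
#' Parameters present in `reference` but absent from `intakes` are skipped
#' (the index is defined on whatever subset is available); computing on a
#' subset is identical to zeroing the excluded parameters' effect scores.
#'
#' @param intakes data.frame with `participant_id` plus one column per
#'   dietary parameter (daily intakes), e.g. from [nutrient_intakes()].
#' @param reference Reference table as from [generate_reference_table()].
#' @param method Percentile method, see [centered_percentile()].
#' @param units_scale Scalar multiplier applied to intakes before scoring
#'   (default 1), for inputs recorded on a different per-unit basis.
#' @param quartiles If `TRUE` (default) and the cohort has >= 4 members,
#'   attach cohort-relative quartiles.
#' @return An object of class `dii_result`: a list with `scores`
#'   (participants x parameters matrix of parameter-specific scores), `z`,
#'   `centered_percentile`, and a data.frame `dii` with `participant_id`,
#'   `dii` and optionally `quartile`.
#' @export
compute_dii <- function(intakes, reference,
                        method = c("normal_cdf", "empirical"),
                        units_scale = 1, quartiles = TRUE) {
  method <- match.arg(method)
  validate_reference(reference)
  assert_that("participant_id" %in% names(intakes),
              "intakes must carry a participant_id column")
  assert_that(is.numeric(units_scale) && units_scale > 0,
              "units_scale must be a positive scalar")

  params <- intersect(reference$parameter, names(intakes))
  assert_that(length(params) >= 1,
              "no reference parameter found among intake columns")
  ref <- reference[match(params, reference$parameter), ]
  x <- as.matrix(intakes[, params, drop = FALSE]) * units_scale

  z <- sweep(sweep(x, 2, ref$global_mean, "-"), 2, ref$global_sd, "/")
  if (method == "normal_cdf") {
    cp <- 2 * stats::pnorm(z) - 1
  } else {
    cp <- apply(z, 2, centered_percentile, method = "empirical")
    if (is.null(dim(cp))) cp <- matrix(cp, nrow = nrow(z),
                                       dimnames = dimnames(z))
  }
  scores <- sweep(cp, 2, ref$effect_score, "*")
  overall <- rowSums(scores)

  dii <- data.frame(participant_id = intakes$participant_id, dii = overall,
                    stringsAsFactors = FALSE)
  if (quartiles && nrow(dii) >= 4) dii$quartile <- dii_quartiles(overall)

  structure(list(parameters = params, method = method,
                 z = z, centered_percentile = cp, scores = scores, dii = dii),
            class = "dii_result")
}

#' @export
print.dii_result <- function(x, ...) {
  cat(sprintf("DII scores for %d participants over %d parameters (%s)\n",
              nrow(x$dii), length(x$parameters), x$method))
  cat(sprintf("  overall DII: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              mean(x$dii$dii), stats::sd(x$dii$dii),
              min(x$dii$dii), max(x$dii$dii)))
  invisible(x)
}
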