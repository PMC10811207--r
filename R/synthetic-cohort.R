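## Synthetic cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## correlated log-normal food intakes, a sparse shared food-composition
## matrix (nutrients nested in foods), a DII derived from nutrient intakes,
## covariates on a realistic cross-sectional mix, and continuous outcomes
## generated from the three-level hierarchy
##     outcome = alpha + C c + F_std beta + noise,
##     beta = Z pi + delta,   pi = w gamma + theta,
## with the ground truth (gamma, beta, pi, delta, theta) recorded separately
## for parameter-recovery testing. Outcomes are clipped and rounded to the
## DASS subscale support [0, 42]; the pre-clip latent values are kept because
## the linear model is exact only before clipping.

# Default covariate effect sizes (outcome points per unit/level), on the
# reduced covariate set, chosen to be realistic for DASS-type outcomes in a
# large occupational cohort. Order matches the generated covariate columns.
default_covariate_effects <- c(
  female = 2.735, education = -0.078, smoking = 0.349,
  ses_childhood = 0.900, ses_self = -0.740, ses_fluctuation = 0.432,
  liver_disease = 1.878, hypothyroidism = 0.778, cvd = 1.176,
  diabetes = 0.367, asset = -0.064, social_activity = -0.389)

#' Simulation configuration for the synthetic cohort
#'
#' @param n_participants Cohort size before any exclusion.
#' @param n_foods Number of FFQ food items (default 116).
#' @param n_nutrients Number of dietary parameters (default 25).
#' @param true_dii_effects Named vector: the true effect of the diet-level
#'   composite on each outcome, in outcome points per unit of the
#'   standardized composite `F_std %*% Z_std %*% w`. Defaults are scaled so
#'   the dietary signal contributes about 1.5 outcome points SD, a realistic
#'   share for diet in mental-health outcomes (see the methods vignette).
#' @param covariate_effects Named vector of covariate effects; must match the
#'   generated covariate columns.
#' @param intercepts Named vector of outcome intercepts (outcome points at
#'   sample-mean covariates and foods).
#' @param food_residual_sd SD of the food-level residual effects `delta`.
#' @param nutrient_residual_sd SD of the nutrient-level residuals `theta`.
#' @param outcome_noise_sd Residual SD of the outcome (> 0).
#' @param intake_correlation Compound-symmetry correlation of the latent
#'   Gaussian driving food intakes, in `[0, 1)`.
#' @param outlier_energy_fraction Fraction of participants given implausible
#'   (high) energy intakes to exercise the exclusion filter.
#' @param include_items Generate DASS-42 item responses (default TRUE).
#' @param include_ffq Generate the long FFQ table (default TRUE).
#' @param seed Integer seed; all sub-generators derive from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants,
                              n_foods = 116L,
                              n_nutrients = 25L,
                              true_dii_effects = c(stress = 0.10,
                                                   anxiety = 0.12,
                                                   depression = 0.085),
                              covariate_effects = default_covariate_effects,
                              intercepts = c(stress = 13.6, anxiety = 6.2,
                                             depression = 8.0),
                              food_residual_sd = 0.1,
                              nutrient_residual_sd = 0.1,
                              outcome_noise_sd = 8,
                              intake_correlation = 0.3,
                              outlier_energy_fraction = 0.014,
                              include_items = TRUE,
                              include_ffq = TRUE,
                              seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_foods = as.integer(n_foods),
              n_nutrients = as.integer(n_nutrients),
              true_dii_effects = true_dii_effects,
              covariate_effects = covariate_effects,
              intercepts = intercepts,
              food_residual_sd = food_residual_sd,
              nutrient_residual_sd = nutrient_residual_sd,
              outcome_noise_sd = outcome_noise_sd,
              intake_correlation = intake_correlation,
              outlier_energy_fraction = outlier_energy_fraction,
              include_items = isTRUE(include_items),
              include_ffq = isTRUE(include_ffq),
              seed = as.integer(seed))
  assert_that(cfg$n_participants >= 2, "n_participants must be >= 2")
  assert_that(cfg$n_foods >= 2, "n_foods must be >= 2")
  assert_that(cfg$n_nutrients >= 1, "n_nutrients must be >= 1")
  outs <- c("stress", "anxiety", "depression")
  assert_that(all(outs %in% names(cfg$true_dii_effects)),
              "true_dii_effects must name stress, anxiety, depression")
  assert_that(all(outs %in% names(cfg$intercepts)),
              "intercepts must name stress, anxiety, depression")
  assert_that(cfg$food_residual_sd >= 0 && cfg$nutrient_residual_sd >= 0,
              "residual SDs must be non-negative")
  assert_that(cfg$outcome_noise_sd > 0, "outcome_noise_sd must be > 0")
  assert_that(cfg$intake_correlation >= 0 && cfg$intake_correlation < 1,
              "intake_correlation must be in [0, 1)")
  assert_that(cfg$outlier_energy_fraction >= 0 &&
                cfg$outlier_energy_fraction < 1,
              "outlier_energy_fraction must be in [0, 1)")
  structure(cfg, class = "simulation_config")
}

# Covariate sampler: a reduced cross-sectional covariate set (one binary
# gender, ordinal education/smoking/socio-economic scales, four binary
# diseases, two continuous standardized composites) with category frequencies
# typical of a large university-employee cohort.
generate_covariates <- function(n, seed) {
  set.seed(seed)
  samp <- function(probs) sample.int(length(probs), n, TRUE, probs)
  data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    female = stats::rbinom(n, 1, 0.611),
    education = samp(c(0.5, 3.7, 4.3, 18.7, 8.3, 38.2, 20.9, 5.3)),
    smoking = samp(c(67.9, 1.4, 5.2, 0.7, 12.4, 7.5, 2.7, 2.1)),
    ses_childhood = samp(c(4.3, 17.3, 49.1, 15.9, 13.4)),
    ses_self = samp(c(4.5, 26.4, 53.6, 11.9, 3.6)),
    ses_fluctuation = samp(c(4.2, 13.4, 22.5, 18.9, 41.0)),
    liver_disease = stats::rbinom(n, 1, 0.053),
    hypothyroidism = stats::rbinom(n, 1, 0.115),
    cvd = stats::rbinom(n, 1, 0.069),
    diabetes = stats::rbinom(n, 1, 0.043),
    asset = stats::rnorm(n),
    social_activity = stats::rnorm(n),
    stringsAsFactors = FALSE)
}

# DASS-42 items consistent with given subscale totals: for a total T, draw T
# of the subscale's 42 point-slots (14 items x 3 points) without replacement;
# item counts are automatically capped at 3 and sum exactly to T.
generate_dass_items <- function(outcomes, key, seed) {
  set.seed(seed)
  n <- nrow(outcomes)
  items <- matrix(0L, n, 42, dimnames = list(NULL, sprintf("item_%d", 1:42)))
  for (sub in c("stress", "anxiety", "depression")) {
    idx <- key$item[key$subscale == sub]
    tot <- outcomes[[sub]]
    for (i in seq_len(n)) {
      if (tot[i] > 0) {
        slots <- sample.int(42, tot[i])
        items[i, idx] <- tabulate(ceiling(slots / 3), nbins = 14L)
      }
    }
  }
  cbind(data.frame(participant_id = outcomes$participant_id,
                   stringsAsFactors = FALSE),
        as.data.frame(items))
}

#' Generate a synthetic cohort
#'
#' @param config A [simulation_config()].
#' @param reference Reference-parameter table with `config$n_nutrients` rows,
#'   e.g. from [generate_reference_table()].
#' @return A list of class `dii_cohort` with the five input tables (`ffq`,
#'   `composition`, `reference`, `covariates`, `dass_items`), intermediate
#'   tables (`grams`, `intakes`, `outcomes`, `latent`, `dii`) and a
#'   `simulation_truth` object `truth` holding `gamma`, `beta`, `pi`,
#'   `delta`, `theta`, the planted outlier ids and the noise parameters.
#' @export
generate_cohort <- function(config, reference) {
  assert_that(inherits(config, "simulation_config"),
              "config must come from simulation_config()")
  validate_reference(reference)
  assert_that(nrow(reference) == config$n_nutrients,
              "reference has %d rows but config expects %d nutrients",
              nrow(reference), config$n_nutrients)

  n <- config$n_participants
  J <- config$n_foods
  I <- config$n_nutrients
  ids <- sprintf("P%05d", seq_len(n))
  foods <- sprintf("food_%03d", seq_len(J))
  outs <- c("stress", "anxiety", "depression")

  ## --- composition matrix: I nutrients per 100 g of J foods, ~70% sparse --
  set.seed(derive_seed(config$seed, 1L))
  comp <- matrix(stats::rlnorm(J * I, 0, 1), J, I,
                 dimnames = list(foods, reference$parameter))
  mask <- matrix(stats::rbinom(J * I, 1, 0.30), J, I)
  if ("energy_kcal" %in% reference$parameter)  # every food carries energy
    mask[, reference$parameter == "energy_kcal"] <- 1L
  # every nutrient occurs in >= 2 foods, every food has >= 1 nutrient
  for (k in seq_len(I)) {
    if (sum(mask[, k]) < 2) mask[sample.int(J, 2), k] <- 1L
  }
  empty <- which(rowSums(mask) == 0)
  if (length(empty)) mask[cbind(empty, sample.int(I, length(empty), TRUE))] <- 1L
  comp <- comp * mask

  ## --- daily grams: correlated log-normal intakes -------------------------
  set.seed(derive_seed(config$seed, 2L))
  rho <- config$intake_correlation
  shared <- stats::rnorm(n)
  x <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(n * J), n, J)
  food_scale <- stats::rlnorm(J, log(30), 0.8)
  grams <- sweep(exp(0.6 * x), 2, food_scale, "*")
  dimnames(grams) <- list(NULL, foods)

  ## --- calibrate composition so cohort intakes sit near the reference ----
  # Cohort means land within ~15% (log scale) of the reference global means,
  # so Z-scores and percentiles are exercised over their useful range.
  set.seed(derive_seed(config$seed, 3L))
  raw <- (grams / 100) %*% comp
  target <- reference$global_mean * exp(stats::rnorm(I, 0, 0.15))
  comp <- sweep(comp, 2, target / colMeans(raw), "*")
  intake_mat <- (grams / 100) %*% comp

  ## --- plant energy outliers (high side) ---------------------------------
  set.seed(derive_seed(config$seed, 4L))
  n_out <- round(config$outlier_energy_fraction * n)
  outlier_ids <- character(0)
  if (n_out > 0) {
    assert_that("energy_kcal" %in% reference$parameter,
                "outlier planting needs an energy_kcal parameter")
    e <- intake_mat[, "energy_kcal"]
    who <- sample.int(n, n_out)
    sep <- stats::runif(n_out, 12, 20)  # 12-20 clean SDs above the mean
    factor <- (mean(e) + sep * stats::sd(e)) / e[who]
    grams[who, ] <- grams[who, , drop = FALSE] * factor
    intake_mat <- (grams / 100) %*% comp
    outlier_ids <- ids[who]
  }
  # The generator states the rule-violating fraction rather than sampling it:
  # non-planted participants whose energy would trip the +/-3 SD rule (heavy
  # log-normal tails produce one in a few thousand) are damped toward the
  # non-planted mean so the violation set is exactly the planted set.
  planted <- ids %in% outlier_ids
  for (iter in if ("energy_kcal" %in% reference$parameter) 1:10 else integer(0)) {
    e <- intake_mat[, "energy_kcal"]
    viol <- abs(e - mean(e)) > 3 * stats::sd(e) & !planted
    if (!any(viol)) break
    m0 <- mean(e[!planted]); s0 <- stats::sd(e[!planted])
    tgt <- m0 + sign(e[viol] - m0) * 2 * s0
    grams[viol, ] <- grams[viol, , drop = FALSE] * (tgt / e[viol])
    intake_mat <- (grams / 100) %*% comp
  }

  ## --- hierarchy truth ----------------------------------------------------
  set.seed(derive_seed(config$seed, 5L))
  Zs <- standardize_columns(comp, "composition")$x      # foods x nutrients
  w <- reference$effect_score
  delta <- stats::rnorm(J, 0, config$food_residual_sd)
  theta <- stats::rnorm(I, 0, config$nutrient_residual_sd)
  gamma <- config$true_dii_effects[outs]
  pi_mat <- outer(w, gamma) + theta                     # nutrients x outcomes
  beta_mat <- Zs %*% pi_mat + delta                     # foods x outcomes
  colnames(pi_mat) <- colnames(beta_mat) <- outs

  ## --- covariates and outcomes -------------------------------------------
  covariates <- generate_covariates(n, derive_seed(config$seed, 6L))
  cov_cols <- names(config$covariate_effects)
  assert_that(all(cov_cols %in% names(covariates)),
              "covariate_effects name unknown covariates")
  C <- scale(as.matrix(covariates[cov_cols]), scale = FALSE)  # centered
  Fs <- standardize_columns(grams, "food grams")$x
  composite <- as.vector(Fs %*% Zs %*% w)

  set.seed(derive_seed(config$seed, 7L))
  lin_cov <- as.vector(C %*% config$covariate_effects[cov_cols])
  latent <- sapply(outs, function(k) {
    config$intercepts[[k]] + lin_cov + as.vector(Fs %*% beta_mat[, k]) +
      stats::rnorm(n, 0, config$outcome_noise_sd)
  })
  observed <- pmin(pmax(round(latent), 0), 42)

  outcomes <- data.frame(participant_id = ids, observed,
                         stringsAsFactors = FALSE)
  latent_df <- data.frame(participant_id = ids, latent,
                          stringsAsFactors = FALSE)

  dass_items <- NULL
  if (config$include_items)
    dass_items <- generate_dass_items(outcomes, dass42_key(),
                                      derive_seed(config$seed, 8L))

  ## --- FFQ long table (round-trips to the grams matrix) -------------------
  ffq <- NULL
  if (config$include_ffq) {
    set.seed(derive_seed(config$seed, 9L))
    portion <- stats::runif(J, 15, 300)
    period <- sample(c("day", "week", "month"), n * J, TRUE,
                     prob = c(0.2, 0.5, 0.3))
    ffq <- data.frame(
      participant_id = rep(ids, times = J),
      food_id = rep(foods, each = n),
      frequency = as.vector(grams) * period_days[period] / rep(portion, each = n),
      period = period,
      portion_grams = rep(portion, each = n),
      stringsAsFactors = FALSE)
  }

  intakes <- cbind(data.frame(participant_id = ids, stringsAsFactors = FALSE),
                   as.data.frame(intake_mat, check.names = FALSE))
  dii <- compute_dii(intakes, reference)$dii

  truth <- structure(list(
    dii_effect_per_outcome = gamma,
    food_coefficients = beta_mat,
    nutrient_coefficients = pi_mat,
    delta = delta, theta = theta,
    composite = composite,
    covariate_effects = config$covariate_effects[cov_cols],
    intercepts = config$intercepts[outs],
    food_residual_sd = config$food_residual_sd,
    nutrient_residual_sd = config$nutrient_residual_sd,
    outcome_noise_sd = config$outcome_noise_sd,
    outlier_ids = sort(outlier_ids)), class = "simulation_truth")

  structure(list(
    config = config,
    reference = reference,
    composition = cbind(data.frame(food_id = foods, stringsAsFactors = FALSE),
                        as.data.frame(comp, check.names = FALSE)),
    grams = cbind(data.frame(participant_id = ids, stringsAsFactors = FALSE),
                  as.data.frame(grams, check.names = FALSE)),
    intakes = intakes,
    covariates = covariates,
    outcomes = outcomes,
    latent = latent_df,
    dass_items = dass_items,
    ffq = ffq,
    dii = dii,
    truth = truth), class = "dii_cohort")
}

#' @export
print.dii_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d participants, %d foods, %d parameters\n",
              x$config$n_participants, x$config$n_foods,
              x$config$n_nutrients))
  cat(sprintf("  planted energy outliers: %d\n",
              length(x$truth$outlier_ids)))
  cat(sprintf("  DII: mean %.3f sd %.3f\n", mean(x$dii$dii),
              stats::sd(x$dii$dii)))
  invisible(x)
}

#' Write a cohort's input tables to disk
#'
#' Writes `ffq.csv`, `composition.csv`, `reference.csv`, `covariates.csv`,
#' `dass_items.csv` and `truth.json` into `dir`. These files are everything
#' the downstream pipeline needs; intakes, outcomes and DII are recomputed
#' from them.
#'
#' @param cohort A `dii_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "dii_cohort"), "not a dii_cohort")
  assert_that(!is.null(cohort$ffq) && !is.null(cohort$dass_items),
              "cohort was generated without ffq/items tables")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ffq = file.path(dir, "ffq.csv"),
             composition = file.path(dir, "composition.csv"),
             reference = file.path(dir, "reference.csv"),
             covariates = file.path(dir, "covariates.csv"),
             dass_items = file.path(dir, "dass_items.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(cohort$ffq, paths["ffq"], row.names = FALSE)
  utils::write.csv(cohort$composition, paths["composition"], row.names = FALSE)
  utils::write.csv(cohort$reference, paths["reference"], row.names = FALSE)
  utils::write.csv(cohort$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(cohort$dass_items, paths["dass_items"], row.names = FALSE)
  truth <- cohort$truth
  truth$food_coefficients <- as.data.frame(truth$food_coefficients)
  truth$nutrient_coefficients <- as.data.frame(truth$nutrient_coefficients)
  # named vectors serialize as bare arrays; keep the names as object keys
  truth$dii_effect_per_outcome <- as.list(truth$dii_effect_per_outcome)
  truth$covariate_effects <- as.list(truth$covariate_effects)
  truth$intercepts <- as.list(truth$intercepts)
  jsonlite::write_json(unclass(truth), paths["truth"], digits = NA,
                       auto_unbox = TRUE)
  invisible(paths)
}
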