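# Synthetic cohort generator: determinism, the hierarchy identities that
# define the simulation truth, and recovery of configured quantities.

test_that("reference table generation is deterministic with valid shape", {
  ref <- generate_reference_table(25, seed = 1)
  expect_equal(nrow(ref), 25)
  expect_true(all(ref$global_sd > 0))
  expect_true(all(abs(ref$effect_score) <= 1))
  expect_equal(ref$parameter, dii_parameters$parameter)

  one <- generate_reference_table(1, seed = 7)
  expect_equal(nrow(one), 1)
  expect_identical(one, generate_reference_table(1, seed = 7))

  # configured anti-inflammatory fraction, exact count
  expect_equal(sum(generate_reference_table(25, 1, anti_fraction = 0.45)$
                     effect_score < 0), round(0.45 * 25))
  expect_equal(sum(generate_reference_table(30, 3, anti_fraction = 0.2)$
                     effect_score < 0), 6)

  expect_error(generate_reference_table(0), "positive")
})

test_that("identical (config, seed) pairs reproduce the cohort exactly", {
  ref <- small_reference()
  cfg <- simulation_config(60, n_foods = 15, n_nutrients = 10, seed = 5)
  a <- generate_cohort(cfg, ref)
  b <- generate_cohort(cfg, ref)
  for (tab in c("ffq", "composition", "intakes", "covariates", "outcomes",
                "dass_items", "latent"))
    expect_identical(a[[tab]], b[[tab]], label = tab)
  expect_identical(a$truth, b$truth)
})

test_that("simulation truth satisfies the two nesting identities exactly", {
  sc <- small_cohort(n = 80)
  tr <- sc$cohort$truth
  Zs <- scale(as.matrix(sc$cohort$composition[-1]))
  resid_beta <- tr$food_coefficients -
    (Zs %*% tr$nutrient_coefficients +
       matrix(tr$delta, nrow(Zs), 3))
  expect_lt(max(abs(resid_beta)), 1e-12)
  resid_pi <- tr$nutrient_coefficients -
    (outer(sc$ref$effect_score, tr$dii_effect_per_outcome) +
       matrix(tr$theta, 10, 3))
  expect_lt(max(abs(resid_pi)), 1e-12)
})

test_that("intakes obey the composition identity and config validation works", {
  sc <- small_cohort(n = 40)
  co <- sc$cohort
  expect_equal(as.matrix(co$intakes[-1]),
               (as.matrix(co$grams[-1]) / 100) %*%
                 as.matrix(co$composition[-1]),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(simulation_config(50, intake_correlation = 1), "\\[0, 1\\)")
  expect_error(simulation_config(50, outcome_noise_sd = 0), "> 0")
  expect_error(simulation_config(50, food_residual_sd = -1), "non-negative")
  ref5 <- generate_reference_table(5, 1)
  expect_error(generate_cohort(simulation_config(50), ref5), "25 nutrients")
})

test_that("with residuals and noise off, outcomes are linear in the composite", {
  sc <- small_cohort(n = 100, food_residual_sd = 0, nutrient_residual_sd = 0,
                     outcome_noise_sd = 1e-10, outlier_energy_fraction = 0,
                     include_items = FALSE, include_ffq = FALSE)
  co <- sc$cohort
  tr <- co$truth
  fit <- lm(co$latent$stress ~ tr$composite +
              as.matrix(co$covariates[names(sc$cfg$covariate_effects)]))
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_equal(unname(coef(fit)[2]), unname(tr$dii_effect_per_outcome["stress"]),
               tolerance = 1e-6)
})

test_that("OLS on the true composite recovers the configured effect on average", {
  # scaled-down simulation oracle: average estimate over replicates within
  # 3 Monte-Carlo standard errors of the configured coefficient
  ref <- small_reference()
  ests <- vapply(1:40, function(i) {
    cfg <- simulation_config(800, n_foods = 20, n_nutrients = 10,
                             outlier_energy_fraction = 0,
                             include_items = FALSE, include_ffq = FALSE,
                             seed = 7000 + i)
    co <- generate_cohort(cfg, ref)
    X <- cbind(co$truth$composite,
               as.matrix(co$covariates[names(cfg$covariate_effects)]))
    unname(coef(lm(co$latent$stress ~ X))[2])
  }, 0)
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.10), 3 * mc_se)
})

test_that("planted energy outlier fraction matches the configuration", {
  sc <- small_cohort(n = 400, outlier_energy_fraction = 0.05,
                     include_items = FALSE, include_ffq = FALSE)
  expect_length(sc$cohort$truth$outlier_ids, round(0.05 * 400))
  res <- energy_exclusion(sc$cohort$intakes)
  expect_setequal(res$excluded_ids, sc$cohort$truth$outlier_ids)
})

test_that("written cohort tables land on disk and truth survives JSON", {
  sc <- small_cohort(n = 12)
  dir <- file.path(tempdir(), "cohort-write-test")
  paths <- write_cohort(sc$cohort, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$dii_effect_per_outcome[["stress"]], 0.10)
  expect_length(truth$delta, 20)
  unlink(dir, recursive = TRUE)
})
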