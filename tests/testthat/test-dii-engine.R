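# DII engine: Z-scores, centered percentiles, weighting, summation,
# quartiles, and the index's structural invariants.

test_that("z-scores and centered percentiles follow their closed forms", {
  expect_equal(dii_z_score(5, 5, 2), 0)
  expect_equal(dii_z_score(2, 1, 0.5), 2)
  expect_equal(dii_z_score(0, 10, 4), -2.5)
  expect_error(dii_z_score(1, 0, 0), "positive")

  expect_equal(centered_percentile(0), 0)
  expect_equal(centered_percentile(50), 1, tolerance = 1e-12)
  expect_equal(centered_percentile(-50), -1, tolerance = 1e-12)
  # 2 Phi(1) - 1, standard normal CDF oracle
  expect_equal(centered_percentile(1), 2 * pnorm(1) - 1)
  expect_equal(centered_percentile(1), 0.68269, tolerance = 1e-5)

  # empirical method: (rank - 0.5)/n, mean exactly zero
  z <- c(3, -1, 0.5, 2, -2)
  cp <- centered_percentile(z, "empirical")
  expect_equal(mean(cp), 0)
  expect_equal(cp[order(z)], 2 * ((1:5 - 0.5) / 5) - 1)
  expect_error(centered_percentile(1, "empirical"), "size >= 2")
})

test_that("parameter scores multiply percentile by effect score; overall sums", {
  expect_equal(parameter_score(0, 0.9), 0)
  expect_equal(parameter_score(0.5, -0.4), -0.2)
  expect_equal(parameter_score(-1, 0.3), -0.3)
  expect_error(parameter_score(1.5, 0.3), "\\[-1, 1\\]")

  expect_equal(overall_dii(c(0, 0, 0)), 0)
  expect_equal(overall_dii(c(0.2, -0.5, 0.1)), -0.2)
  expect_error(overall_dii(numeric(0)), "no parameter")
})

test_that("quartiles are rank-based with ties to the lower quartile", {
  expect_equal(dii_quartiles(1:8), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(dii_quartiles(rep(5, 6)), rep(1L, 6))
  expect_error(dii_quartiles(1:3), "at least 4")

  set.seed(3)
  q <- dii_quartiles(runif(1000))
  expect_equal(as.vector(table(q)), rep(250L, 4))
})

test_that("compute_dii: reference-mean intakes score zero on every parameter", {
  ref <- small_reference(8)
  intakes <- data.frame(participant_id = "p1",
                        as.list(setNames(ref$global_mean, ref$parameter)),
                        check.names = FALSE)
  res <- compute_dii(intakes, ref, quartiles = FALSE)
  expect_equal(unname(res$scores[1, ]), rep(0, 8))
  expect_equal(res$dii$dii, 0)
})

test_that("overall DII is bounded and equals the row sum of parameter scores", {
  sc <- small_cohort(n = 120, include_items = FALSE, include_ffq = FALSE)
  res <- compute_dii(sc$cohort$intakes, sc$ref)
  expect_true(all(abs(res$centered_percentile) <= 1))
  expect_equal(res$dii$dii, rowSums(res$scores))
  expect_true(all(abs(res$dii$dii) <= sum(abs(sc$ref$effect_score)) + 1e-12))
})

test_that("DII is monotone in intake, direction set by the effect score sign", {
  ref <- small_reference(6)
  set.seed(9)
  intakes <- data.frame(participant_id = sprintf("p%d", 1:5),
                        sapply(setNames(nm = ref$parameter), function(p) {
                          m <- ref$global_mean[ref$parameter == p]
                          abs(rnorm(5, m, m / 3))
                        }), check.names = FALSE)
  base <- compute_dii(intakes, ref, quartiles = FALSE)$dii$dii
  pro <- ref$parameter[ref$effect_score > 0][1]
  anti <- ref$parameter[ref$effect_score < 0][1]
  up_pro <- intakes; up_pro[[pro]] <- up_pro[[pro]] + 1
  up_anti <- intakes; up_anti[[anti]] <- up_anti[[anti]] + 1
  expect_true(all(compute_dii(up_pro, ref, quartiles = FALSE)$dii$dii > base))
  expect_true(all(compute_dii(up_anti, ref, quartiles = FALSE)$dii$dii < base))
})

test_that("subsetting parameters equals zeroing their effect scores", {
  sc <- small_cohort(n = 50, include_items = FALSE, include_ffq = FALSE)
  ref <- sc$ref
  keep <- ref$parameter[c(1, 3, 5, 7)]
  sub <- compute_dii(sc$cohort$intakes[c("participant_id", keep)], ref,
                     quartiles = FALSE)
  zeroed_ref <- ref
  zeroed_ref$effect_score[!zeroed_ref$parameter %in% keep] <- 0
  full <- compute_dii(sc$cohort$intakes, zeroed_ref, quartiles = FALSE)
  expect_equal(sub$dii$dii, full$dii$dii, tolerance = 1e-12)
})

test_that("DII is invariant to shifting an intake and its global mean together", {
  sc <- small_cohort(n = 50, include_items = FALSE, include_ffq = FALSE)
  ref <- sc$ref
  base <- compute_dii(sc$cohort$intakes, ref, quartiles = FALSE)$dii$dii
  shift <- 123.4
  ref2 <- ref
  ref2$global_mean[2] <- ref2$global_mean[2] + shift
  intakes2 <- sc$cohort$intakes
  intakes2[[ref$parameter[2]]] <- intakes2[[ref$parameter[2]]] + shift
  expect_equal(compute_dii(intakes2, ref2, quartiles = FALSE)$dii$dii, base,
               tolerance = 1e-12)
})

test_that("empirical percentiles have cohort mean ~ 0 per parameter", {
  sc <- small_cohort(n = 200, include_items = FALSE, include_ffq = FALSE)
  res <- compute_dii(sc$cohort$intakes, sc$ref, method = "empirical")
  expect_true(all(abs(colMeans(res$centered_percentile)) < 2 / 200))
})
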