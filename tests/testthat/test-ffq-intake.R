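# FFQ conversion, nutrient additivity and the energy exclusion rule.

test_that("daily_grams normalizes frequencies by period length", {
  expect_equal(daily_grams(7, "week", 100), 100)
  expect_equal(daily_grams(0, "month", 250), 0)
  expect_equal(daily_grams(1, "day", 80), 80)
  # 3 servings of 150 g per 30.44-day month
  expect_equal(daily_grams(3, "month", 150), 3 * 150 / 30.44)
  expect_equal(daily_grams(3, "month", 150), 14.783, tolerance = 1e-4)
  expect_equal(daily_grams(2, "year", 365.25), 2)

  expect_error(daily_grams(1, "fortnight", 10), "unknown frequency period")
  expect_error(daily_grams(-1, "week", 10), "non-negative")
  expect_error(daily_grams(1, "week", -10), "non-negative")
})

test_that("nutrient intakes are (grams/100) x composition, additive over foods", {
  comp <- matrix(c(3, 2, 1), 3, 1,
                 dimnames = list(c("a", "b", "c"), "nutrient_x"))
  g1 <- matrix(100, 1, 1, dimnames = list(NULL, "a"))
  expect_equal(nutrient_intakes(g1, comp)[1, "nutrient_x"], 3)

  g0 <- matrix(0, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(nutrient_intakes(g0, comp) == 0))

  # two foods at 50 and 200 g/day with 2 and 1 units per 100 g -> 3 units/day
  comp2 <- matrix(c(2, 1), 2, 1, dimnames = list(c("a", "b"), "x"))
  g2 <- matrix(c(50, 200), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(nutrient_intakes(g2, comp2)[1, "x"]), 3.0)

  # additivity: joint intake equals the sum of single-food intakes
  ga <- g2; ga[, "b"] <- 0
  gb <- g2; gb[, "a"] <- 0
  expect_equal(nutrient_intakes(g2, comp2),
               nutrient_intakes(ga, comp2) + nutrient_intakes(gb, comp2))

  expect_error(nutrient_intakes(
    matrix(1, 1, 1, dimnames = list(NULL, "mystery_food")), comp),
    "mystery_food")
})

test_that("ffq_daily_grams round-trips the generator's grams matrix", {
  sc <- small_cohort(n = 40)
  g <- ffq_daily_grams(sc$cohort$ffq)
  g <- g[match(sc$cohort$grams$participant_id, g$participant_id),
         names(sc$cohort$grams)]
  expect_equal(as.matrix(g[-1]), as.matrix(sc$cohort$grams[-1]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("intakes are invariant to participant/food order and scale with portions", {
  sc <- small_cohort(n = 30)
  ffq <- sc$cohort$ffq
  comp <- sc$cohort$composition
  base <- nutrient_intakes(ffq_daily_grams(ffq), comp)
  base <- base[order(base$participant_id), ]

  perm <- ffq[sample.int(nrow(ffq)), ]
  shuf <- nutrient_intakes(ffq_daily_grams(perm), comp)
  shuf <- shuf[order(shuf$participant_id), names(base)]
  expect_equal(shuf, base, ignore_attr = TRUE)

  doubled <- ffq
  doubled$portion_grams <- doubled$portion_grams * 2
  two <- nutrient_intakes(ffq_daily_grams(doubled), comp)
  two <- two[order(two$participant_id), ]
  expect_equal(as.matrix(two[-1]), 2 * as.matrix(base[-1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("energy exclusion applies the single-pass 3 SD rule", {
  # identical energies: SD 0, nobody excluded
  same <- data.frame(participant_id = sprintf("p%d", 1:100),
                     energy_kcal = rep(2000, 100))
  expect_length(energy_exclusion(same)$excluded_ids, 0)

  # one extreme value among ten moderate ones: brute-force mean/SD check
  e <- c(rep(100, 10), 10000)
  tab <- data.frame(participant_id = sprintf("p%d", 1:11), energy_kcal = e)
  expect_true(abs(10000 - mean(e)) > 3 * sd(e))   # the rule fires for it
  expect_true(all(abs(100 - mean(e)) <= 3 * sd(e)))
  res <- energy_exclusion(tab)
  expect_equal(res$excluded_ids, "p11")
  expect_equal(nrow(res$retained), 10)

  # retained + excluded partitions the input
  expect_setequal(c(res$retained$participant_id, res$excluded_ids),
                  tab$participant_id)

  expect_error(energy_exclusion(tab[1, , drop = FALSE]), "at least 2")
  expect_error(energy_exclusion(data.frame(participant_id = 1:3, kcal = 1:3)),
               "energy column")
})

test_that("exclusion recovers the generator's planted outliers", {
  sc <- small_cohort(n = 500, outlier_energy_fraction = 0.02,
                     include_items = FALSE, include_ffq = FALSE)
  res <- energy_exclusion(sc$cohort$intakes)
  expect_setequal(res$excluded_ids, sc$cohort$truth$outlier_ids)
  expect_length(res$excluded_ids, round(0.02 * 500))
})
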