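# Hierarchical model: closed-form and matrix oracles, limit behavior,
# variance-component estimation, and invariances.

toy_design <- function(n = 50, J = 5, I = 3, seed = 42) {
  set.seed(seed)
  list(F = matrix(rnorm(n * J), n, J, dimnames = list(NULL, paste0("f", 1:J))),
       Z = matrix(rnorm(J * I), J, I, dimnames = list(NULL, paste0("nu", 1:I))),
       w = c(0.4, -0.3, 0.2),
       C = matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2"))),
       y = rnorm(n, 5, 2))
}

test_that("fit_simple matches closed-form OLS", {
  # noiseless line
  x <- c(1, 2, 3, 4)
  f <- fit_simple(2 * x, x)
  expect_equal(f$gamma, 2)
  expect_equal(f$se_gamma, 0)

  # hand-computed slope: x=(0,1,2), y=(1,1,4) -> cov/var = 3/2
  f2 <- fit_simple(c(1, 1, 4), c(0, 1, 2))
  expect_equal(f2$gamma, 1.5)
  expect_equal(f2$coefficients$estimate[1], 2 - 1.5)  # intercept y-bar - b x-bar

  # permutation invariance
  set.seed(1)
  x3 <- rnorm(30); y3 <- 1 + 2 * x3 + rnorm(30)
  ord <- sample.int(30)
  f3 <- fit_simple(y3, x3)
  f4 <- fit_simple(y3[ord], x3[ord])
  expect_equal(f3$coefficients, f4$coefficients)

  expect_error(fit_simple(1:5, rep(1, 5)), "constant")
  expect_error(fit_simple(1:2, 1:2), "at least 3")
})

test_that("fit_multiple drops exact aliases (later columns first) and keeps the fit", {
  set.seed(8)
  n <- 60
  foods <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rnorm(n) + foods %*% c(1, -1, 0.5, 0)
  dii <- rnorm(n)
  dup <- cbind(foods, f_dup = foods[, 2])
  fd <- fit_multiple(y, dii, foods = dup)
  expect_equal(fd$dropped, "f_dup")
  fm <- fit_multiple(y, dii, foods = foods)
  expect_equal(fd$coefficients[fd$coefficients$term != "f_dup", ],
               fm$coefficients, ignore_attr = TRUE)

  # nutrient columns that are exact combinations of foods give way to foods
  nutr <- foods %*% matrix(runif(8), 4, 2)
  colnames(nutr) <- c("n1", "n2")
  fn <- fit_multiple(y, dii, nutrients = nutr, foods = foods)
  expect_setequal(fn$dropped, c("n1", "n2"))

  # orthogonal adjustment leaves the DII coefficient at the simple-fit slope
  x <- rep(c(-1, 1), each = 30)
  orth <- cbind(o1 = rep(c(-1, 1), 30))   # orthogonal to x by construction
  y2 <- 2 * x + rnorm(60)
  expect_equal(fit_multiple(y2, x, covariates = orth)$gamma,
               fit_simple(y2, x)$gamma, tolerance = 1e-10)

  expect_error(fit_multiple(rnorm(5), rnorm(5),
                            foods = matrix(rnorm(25), 5, 5)),
               "hierarchical")
})

test_that("fixed-variance hierarchical fit equals the dense GLS oracle", {
  d <- toy_design()
  t2f <- 0.5; t2n <- 0.3; s2 <- 2
  sp <- hier_spec(d$F, d$Z, d$w, covariates = d$C, tau2_food = t2f,
                  tau2_nutrient = t2n, sigma2 = s2, standardize = FALSE)
  fit <- fit_hierarchical(sp, d$y)

  FZ <- d$F %*% d$Z
  s <- FZ %*% d$w
  X <- cbind(1, d$C, s)
  V <- s2 * diag(nrow(X)) + t2f * tcrossprod(d$F) + t2n * tcrossprod(FZ)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
  r <- d$y - X %*% b
  expect_equal(fit$coefficients$estimate, unname(drop(b)), tolerance = 1e-8)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(solve(t(X) %*% Vi %*% X)))), tolerance = 1e-8)
  expect_equal(fit$delta_hat, unname(drop(t2f * t(d$F) %*% Vi %*% r)),
               tolerance = 1e-8)
  expect_equal(fit$theta_hat, unname(drop(t2n * t(FZ) %*% Vi %*% r)),
               tolerance = 1e-8)
  # reconstruction identities
  expect_equal(fit$foods$beta_std,
               drop(d$Z %*% (d$w * fit$gamma + fit$theta_hat) + fit$delta_hat),
               tolerance = 1e-12)
})

test_that("tau2 = 0 collapses to OLS on the composite score", {
  d <- toy_design(seed = 7)
  sp <- hier_spec(d$F, d$Z, d$w, covariates = d$C,
                  tau2_food = 0, tau2_nutrient = 0, standardize = FALSE)
  fit <- fit_hierarchical(sp, d$y)
  s <- d$F %*% d$Z %*% d$w
  ols <- lm(d$y ~ d$C + s)
  expect_equal(fit$gamma, unname(coef(ols)["s"]), tolerance = 1e-10)
  # beta is exactly the nutrient-predicted value Z w gamma
  expect_equal(fit$foods$beta_std, drop(d$Z %*% d$w) * fit$gamma,
               tolerance = 1e-12)
  expect_equal(fit$tau2, c(food = 0, nutrient = 0))
})

test_that("large tau2 approaches the unpenalized multiple regression", {
  set.seed(11)
  n <- 200; J <- 5; I <- 3
  d <- toy_design(n = n, seed = 11)
  y <- rnorm(n) + d$F %*% rnorm(J)
  sp <- hier_spec(d$F, d$Z, d$w, tau2_food = 1e8, tau2_nutrient = 1e8,
                  sigma2 = 1, standardize = FALSE)
  fit <- fit_hierarchical(sp, y)
  mm <- fit_multiple(y, dii = NULL, foods = d$F)
  bm <- mm$coefficients$estimate[match(colnames(d$F), mm$coefficients$term)]
  expect_equal(fit$foods$beta_std, bm, tolerance = 1e-3)
})

test_that("shrinkage moves food coefficients between the two extremes", {
  # 2-food toy system: as tau2 grows, each beta moves monotonically in norm
  # from its nutrient-predicted value toward the OLS value
  set.seed(13)
  n <- 120
  Fm <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("fa", "fb")))
  Z <- matrix(c(1, 0.5), 2, 1, dimnames = list(NULL, "nu"))
  w <- 1
  y <- drop(Fm %*% c(1.2, -0.4)) + rnorm(n)
  ols <- coef(lm(y ~ Fm))[-1]
  taus <- c(1e-6, 0.01, 0.1, 1, 100)
  dist_ols <- sapply(taus, function(t2) {
    sp <- hier_spec(Fm, Z, w, tau2_food = t2, tau2_nutrient = 0,
                    sigma2 = 1, standardize = FALSE)
    sqrt(sum((fit_hierarchical(sp, y)$foods$beta_std - ols)^2))
  })
  expect_true(all(diff(dist_ols) < 1e-8))  # monotone approach to OLS
})

test_that("REML tau2 estimation is scale-equivariant and near-null at truth 0", {
  sc <- small_cohort(n = 300, food_residual_sd = 0.3, nutrient_residual_sd = 0.3,
                     outlier_energy_fraction = 0,
                     include_items = FALSE, include_ffq = FALSE)
  m <- cohort_matrices(sc)
  sp <- hier_spec(m$G, m$comp, m$w, covariates = m$C)
  y <- sc$cohort$latent$stress
  eb1 <- estimate_tau2_eb(sp, y)
  k <- 3.7
  eb2 <- estimate_tau2_eb(sp, k * y)
  expect_equal(eb2$residual_variance, k^2 * eb1$residual_variance,
               tolerance = 1e-3)
  expect_equal(eb2$tau2_food, k^2 * eb1$tau2_food, tolerance = 1e-2)
  expect_equal(eb2$tau2_nutrient, k^2 * eb1$tau2_nutrient, tolerance = 1e-2)

  # residual-free hierarchy: both estimates should be (near) zero
  sc0 <- small_cohort(n = 400, seed = 77, food_residual_sd = 0,
                      nutrient_residual_sd = 0, outlier_energy_fraction = 0,
                      include_items = FALSE, include_ffq = FALSE)
  m0 <- cohort_matrices(sc0)
  eb0 <- estimate_tau2_eb(hier_spec(m0$G, m0$comp, m0$w, covariates = m0$C),
                          sc0$cohort$latent$stress)
  expect_lt(eb0$tau2_food, 0.05)
  expect_lt(eb0$tau2_nutrient, 0.05)
})

test_that("fits are invariant to participant order and to food relabeling", {
  sc <- small_cohort(n = 150, outlier_energy_fraction = 0,
                     include_items = FALSE, include_ffq = FALSE)
  m <- cohort_matrices(sc)
  y <- sc$cohort$latent$anxiety
  sp <- hier_spec(m$G, m$comp, m$w, covariates = m$C)
  base <- fit_hierarchical(sp, y)

  set.seed(2)
  ord <- sample.int(nrow(m$G))
  sp_p <- hier_spec(m$G[ord, ], m$comp, m$w, covariates = m$C[ord, ])
  perm <- fit_hierarchical(sp_p, y[ord])
  expect_equal(perm$gamma, base$gamma, tolerance = 1e-6)
  expect_equal(perm$se_gamma, base$se_gamma, tolerance = 1e-6)

  fo <- sample.int(ncol(m$G))
  sp_f <- hier_spec(m$G[, fo], m$comp[fo, ], m$w, covariates = m$C)
  relab <- fit_hierarchical(sp_f, y)
  expect_equal(relab$gamma, base$gamma, tolerance = 1e-6)
  expect_equal(relab$foods$beta_std, base$foods$beta_std[fo],
               tolerance = 1e-6)
})

test_that("dimension and validation errors are caught", {
  d <- toy_design()
  expect_error(hier_spec(d$F, d$Z[1:4, ], d$w), "composition has 4 rows")
  expect_error(hier_spec(d$F, d$Z, d$w[1:2]), "2 effect scores")
  expect_error(hier_spec(d$F, d$Z, d$w, tau2_food = -1), "non-negative")
  expect_error(hier_spec(cbind(d$F, const = 1), rbind(d$Z, 0), d$w),
               "constant")
  sp <- hier_spec(d$F, d$Z, d$w, standardize = FALSE)
  expect_error(fit_hierarchical(sp, d$y[1:10]), "length")
})
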