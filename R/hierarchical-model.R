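## Three-level hierarchical regression for nested dietary exposures.
##
## Outcome model:  y = alpha + C c + F beta + eps,        eps ~ N(0, sigma2 I)
## Food level:     beta = Z pi + delta,                 delta ~ N(0, tau2_f I)
## Nutrient level: pi = w gamma + theta,                theta ~ N(0, tau2_n I)
##
## Substituting the two prior stages gives the linear mixed model
##   y = alpha + C c + (F Z w) gamma + (F Z) theta + F delta + eps
## whose marginal covariance is V = sigma2 I + tau2_f F F' + tau2_n (FZ)(FZ)'.
## For a Gaussian outcome with identity link, penalized quasi-likelihood
## coincides with ordinary linear-mixed-model estimation, so the fit is
## computed directly: variance components by restricted maximum likelihood
## (the empirical-Bayes step), fixed effects by GLS, and the residual effects
## delta, theta as posterior means (BLUPs) from Henderson's equations. All
## linear algebra goes through the Woodbury identity on the q = J + I
## random-effect columns, so no n x n matrix is ever formed.

#' Specification of the three-level hierarchical model
#'
#' @param foods Participants x foods matrix of daily grams (column names =
#'   food ids). Standardized internally unless `standardize = FALSE`.
#' @param composition Foods x nutrients bridge (per-100 g composition);
#'   rows must align with the food columns. Standardized per column.
#' @param effect_scores Nutrients x 1 vector of inflammatory effect scores
#'   (the nutrient-to-DII bridge).
#' @param covariates Optional participants x covariates numeric matrix or
#'   data.frame entering the fixed part.
#' @param tau2_food,tau2_nutrient Either the string `"estimate"` (default) or
#'   a fixed non-negative value for the level's random-coefficient variance.
#' @param shared_tau2 When both variances are estimated, estimate a single
#'   common tau2 for both levels (default TRUE, the usual semi-Bayes choice);
#'   set FALSE for separate per-level variances.
#' @param sigma2 Optional fixed residual variance (mainly for oracle tests);
#'   default NULL = estimated.
#' @param max_iterations,tolerance Optimizer budget and relative convergence
#'   tolerance for the REML search.
#' @param standardize Standardize food and composition columns internally
#'   (default TRUE). Disable only when passing pre-standardized designs.
#' @return A list of class `hier_spec`.
#' @export
hier_spec <- function(foods, composition, effect_scores, covariates = NULL,
                      tau2_food = "estimate", tau2_nutrient = "estimate",
                      shared_tau2 = TRUE, sigma2 = NULL,
                      max_iterations = 200L, tolerance = 1e-8,
                      standardize = TRUE) {
  foods <- as.matrix(foods)
  composition <- as.matrix(composition)
  effect_scores <- as.numeric(effect_scores)
  assert_that(ncol(foods) == nrow(composition),
              "foods has %d columns but composition has %d rows",
              ncol(foods), nrow(composition))
  assert_that(ncol(composition) == length(effect_scores),
              "composition has %d columns but %d effect scores supplied",
              ncol(composition), length(effect_scores))
  check_tau2 <- function(x, nm) {
    ok <- (is.character(x) && identical(x, "estimate")) ||
      (is.numeric(x) && length(x) == 1 && x >= 0)
    assert_that(ok, "%s must be \"estimate\" or a non-negative number", nm)
  }
  check_tau2(tau2_food, "tau2_food")
  check_tau2(tau2_nutrient, "tau2_nutrient")
  assert_that(is.numeric(tolerance) && tolerance > 0,
              "tolerance must be positive")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    assert_that(nrow(covariates) == nrow(foods),
                "covariates and foods disagree on participant count")
  }
  if (standardize) {
    fs <- standardize_columns(foods, "food design")
    zs <- standardize_columns(composition, "composition bridge")
    scale_info <- list(food_center = fs$center, food_scale = fs$scale,
                       z_center = zs$center, z_scale = zs$scale)
    foods_std <- fs$x
    z_std <- zs$x
  } else {
    scale_info <- list(food_center = rep(0, ncol(foods)),
                       food_scale = rep(1, ncol(foods)),
                       z_center = rep(0, ncol(composition)),
                       z_scale = rep(1, ncol(composition)))
    foods_std <- foods
    z_std <- composition
  }
  structure(list(foods = foods_std, z = z_std, w = effect_scores,
                 covariates = covariates, tau2_food = tau2_food,
                 tau2_nutrient = tau2_nutrient, shared_tau2 = shared_tau2,
                 sigma2 = sigma2, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, scale_info = scale_info),
            class = "hier_spec")
}

# Cross-product cache for the Woodbury computations.
hier_precompute <- function(X, U, y) {
  list(X = X, U = U, y = y, n = nrow(X), p = ncol(X), q = ncol(U),
       A = crossprod(U), B = crossprod(U, X), uy = drop(crossprod(U, y)),
       XtX = crossprod(X), Xty = drop(crossprod(X, y)),
       yty = sum(y^2))
}

# Core GLS quantities for H = I + U diag(lam) U'. `lam` has one entry per
# random-effect column; entries equal to 0 deactivate their columns exactly.
hier_solve <- function(pc, lam) {
  act <- which(lam > 0)
  if (length(act) == 0) {
    XtHiX <- pc$XtX; XtHiy <- pc$Xty; ytHiy <- pc$yty
    logdetH <- 0
    M <- NULL
  } else {
    K <- pc$A[act, act, drop = FALSE]
    diag(K) <- diag(K) + 1 / lam[act]
    ch <- chol(K)
    M <- chol2inv(ch)
    Ba <- pc$B[act, , drop = FALSE]
    ua <- pc$uy[act]
    XtHiX <- pc$XtX - crossprod(Ba, M %*% Ba)
    XtHiy <- pc$Xty - drop(crossprod(Ba, M %*% ua))
    ytHiy <- pc$yty - drop(crossprod(ua, M %*% ua))
    logdetH <- 2 * sum(log(diag(ch))) + sum(log(lam[act]))
  }
  XtHiX <- (XtHiX + t(XtHiX)) / 2
  b <- solve(XtHiX, XtHiy)
  rss <- ytHiy - drop(crossprod(b, XtHiy))
  rss <- max(rss, .Machine$double.eps)
  list(b = drop(b), rss = rss, XtHiX = XtHiX, logdetH = logdetH,
       logdetXtHiX = determinant(XtHiX, logarithm = TRUE)$modulus,
       M = M, act = act)
}

# Minus twice the restricted log-likelihood, profiled over sigma2 when
# `sigma2` is NULL. `lam` is tau2/sigma2 per random-effect column.
reml_neg2 <- function(pc, lam, sigma2 = NULL) {
  sol <- hier_solve(pc, lam)
  df <- pc$n - pc$p
  if (is.null(sigma2)) {
    s2 <- sol$rss / df
    df * log(s2) + sol$logdetH + as.numeric(sol$logdetXtHiX) + df
  } else {
    df * log(sigma2) + sol$logdetH + as.numeric(sol$logdetXtHiX) +
      sol$rss / sigma2
  }
}

#' Empirical-Bayes (REML) estimation of the level variances
#'
#' Estimates the food-level and nutrient-level random-coefficient variances
#' and the residual variance by maximizing the restricted likelihood of the
#' Gaussian marginal model. The two variances are estimated separately here;
#' [fit_hierarchical()] uses a single shared value by default. Estimates are
#' deterministic given the data. A variance driven to the boundary (0) is
#' returned as exactly 0 with `boundary = TRUE`.
#'
#' @param spec A [hier_spec()].
#' @param outcome Numeric outcome vector.
#' @return Named list: `tau2_food`, `tau2_nutrient`, `residual_variance`,
#'   `boundary`, `neg2_reml`, `n_evaluations`.
#' @export
estimate_tau2_eb <- function(spec, outcome) {
  assert_that(inherits(spec, "hier_spec"), "spec must come from hier_spec()")
  y <- as.numeric(outcome)
  assert_that(length(y) == nrow(spec$foods),
              "outcome length does not match the design")
  d <- hier_design(spec, y)
  pc <- d$pc
  J <- ncol(spec$foods); I <- ncol(spec$z)
  evals <- 0L
  obj <- function(loglam2) {
    evals <<- evals + 1L
    lam <- c(rep(exp(loglam2[1]), J), rep(exp(loglam2[2]), I))
    reml_neg2(pc, lam)
  }
  starts <- list(c(log(1e-2), log(1e-2)), c(log(1e-4), log(1e-4)),
                 c(log(1), log(1)))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = spec$max_iterations * 5,
                                       reltol = spec$tolerance))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # boundary candidates: each lambda pinned to zero (profile the other 1-D)
  prof1 <- stats::optimize(function(l) reml_neg2(pc, c(rep(exp(l), J),
                                                       rep(0, I))),
                           c(-30, 10), tol = 1e-9)
  prof2 <- stats::optimize(function(l) reml_neg2(pc, c(rep(0, J),
                                                       rep(exp(l), I))),
                           c(-30, 10), tol = 1e-9)
  zero <- reml_neg2(pc, rep(0, J + I))
  cands <- list(
    list(lam = exp(best$par), val = best$value),
    list(lam = c(exp(prof1$minimum), 0), val = prof1$objective),
    list(lam = c(0, exp(prof2$minimum)), val = prof2$objective),
    list(lam = c(0, 0), val = zero))
  pick <- cands[[which.min(vapply(cands, `[[`, 0, "val"))]]
  lam2 <- pick$lam
  lam2[lam2 < 1e-10] <- 0                 # numerical boundary -> exact zero
  lamvec <- c(rep(lam2[1], J), rep(lam2[2], I))
  sol <- hier_solve(pc, lamvec)
  s2 <- sol$rss / (pc$n - pc$p)
  list(tau2_food = lam2[1] * s2, tau2_nutrient = lam2[2] * s2,
       residual_variance = s2, boundary = any(lam2 == 0),
       neg2_reml = pick$val, n_evaluations = evals)
}

# Kenward-Roger-style adjusted covariance of the fixed effects, accounting
# for the sampling uncertainty of the estimated variance components. The
# plug-in GLS covariance (X' V^{-1} X)^{-1} treats tau2 and sigma2 as known;
# because the DII coefficient's information comes largely from the J + I
# hierarchy levels rather than from n, ignoring that uncertainty understates
# its standard error appreciably (Kackar-Harville). `blocks` lists the
# column index sets of U whose tau2 was estimated (one entry for a shared
# tau2, two for separate); `sigma_free` says whether sigma2 was estimated.
# All V^{-1} products go through the Woodbury identity (no n x n matrices).
kr_adjusted_cov <- function(pc, lamvec, s2, blocks, sigma_free = TRUE) {
  act <- which(lamvec > 0)
  X <- pc$X
  U <- pc$U
  if (length(act)) {
    Ua <- U[, act, drop = FALSE]
    K <- pc$A[act, act, drop = FALSE]
    diag(K) <- diag(K) + 1 / lamvec[act]
    M <- chol2inv(chol(K))
  }
  vinv <- function(Zm) {
    if (length(act)) (Zm - Ua %*% (M %*% crossprod(Ua, Zm))) / s2
    else Zm / s2
  }
  R <- vinv(X)                     # V^{-1} X, n x p
  Phi <- solve(crossprod(X, R))    # plug-in covariance of the fixed effects
  blocks <- Filter(function(b) all(lamvec[b] > 0), blocks)
  n_th <- length(blocks) + as.integer(sigma_free)
  if (n_th == 0) return(list(cov = Phi, adjusted = FALSE))
  VU <- vinv(U)                    # V^{-1} U, n x q
  V2X <- vinv(R)                   # V^{-2} X, n x p

  GtR <- lapply(blocks, function(b) crossprod(U[, b, drop = FALSE], R))
  P <- vector("list", n_th)
  for (k in seq_along(blocks)) P[[k]] <- crossprod(GtR[[k]])
  if (sigma_free) P[[n_th]] <- crossprod(R)

  Q <- matrix(list(), n_th, n_th)
  Tmat <- matrix(0, n_th, n_th)
  for (k in seq_len(n_th)) {
    for (l in seq_len(n_th)) {
      kb <- k <= length(blocks); lb <- l <= length(blocks)
      if (kb && lb) {
        GVG <- crossprod(U[, blocks[[k]], drop = FALSE],
                         VU[, blocks[[l]], drop = FALSE])
        Q[[k, l]] <- t(GtR[[k]]) %*% GVG %*% GtR[[l]]
        Tmat[k, l] <- sum(GVG^2)
      } else if (kb && !lb) {
        GV2X <- crossprod(U[, blocks[[k]], drop = FALSE], V2X)
        Q[[k, l]] <- t(GtR[[k]]) %*% GV2X
        Tmat[k, l] <- sum(VU[, blocks[[k]], drop = FALSE]^2)
      } else if (!kb && lb) {
        GV2X <- crossprod(U[, blocks[[l]], drop = FALSE], V2X)
        Q[[k, l]] <- t(GV2X) %*% GtR[[l]]
        Tmat[k, l] <- sum(VU[, blocks[[l]], drop = FALSE]^2)
      } else {
        Q[[k, l]] <- crossprod(R, V2X)
        # tr(V^-2) via H^-1 = I - Ua M Ua'
        if (length(act)) {
          MA <- M %*% pc$A[act, act, drop = FALSE]
          Tmat[k, l] <- (pc$n - 2 * sum(diag(MA)) + sum(MA * t(MA))) / s2^2
        } else {
          Tmat[k, l] <- pc$n / s2^2
        }
      }
    }
  }
  info <- matrix(0, n_th, n_th)
  for (k in seq_len(n_th)) for (l in seq_len(n_th)) {
    info[k, l] <- 0.5 * (Tmat[k, l] - 2 * sum(Phi * t(Q[[k, l]])) +
                           sum(diag(Phi %*% P[[k]] %*% Phi %*% P[[l]])))
  }
  W <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(W)) return(list(cov = Phi, adjusted = FALSE))
  mid <- matrix(0, pc$p, pc$p)
  for (k in seq_len(n_th)) for (l in seq_len(n_th)) {
    mid <- mid + W[k, l] * (Q[[k, l]] - P[[k]] %*% Phi %*% P[[l]])
  }
  cov_adj <- Phi + 2 * (Phi %*% mid %*% Phi)
  cov_adj <- (cov_adj + t(cov_adj)) / 2
  # Satterthwaite degrees of freedom per coefficient: the reported variance
  # is itself estimated (it tracks tau2-hat closely), and a normal quantile
  # ignores that noise; df = 2 v^2 / Var(v-hat), Var via the delta method
  # with d v / d omega_k = (Phi P_k Phi)_jj.
  grads <- vapply(seq_len(n_th),
                  function(k) diag(Phi %*% P[[k]] %*% Phi), numeric(pc$p))
  var_v <- rowSums((grads %*% W) * grads)
  df <- ifelse(var_v > 0, 2 * diag(cov_adj)^2 / var_v, Inf)
  list(cov = cov_adj, df = pmax(df, 3), adjusted = TRUE)
}

# Assemble fixed design X = [intercept | covariates | composite] and random
# design U = [F | FZ] for a spec + outcome pair.
hier_design <- function(spec, y) {
  Fm <- spec$foods
  FZ <- Fm %*% spec$z
  s <- drop(FZ %*% spec$w)
  X <- cbind(`(Intercept)` = 1,
             if (!is.null(spec$covariates)) spec$covariates,
             dii = s)
  assert_that(nrow(X) >= ncol(X) + 1,
              "too few participants (%d) for %d fixed effects",
              nrow(X), ncol(X))
  list(pc = hier_precompute(X, cbind(Fm, FZ), y), composite = s,
       X = X, U1 = Fm, U2 = FZ)
}

#' Fit the three-level hierarchical model
#'
#' Fits the Gaussian identity-link mixed model described above for one
#' outcome: the DII-level coefficient `gamma` (fixed), shrunken food and
#' nutrient coefficients, the posterior-mean residual effects `delta_hat`
#' and `theta_hat`, and the variance components. With both level variances
#' fixed at 0 the model collapses exactly to OLS of the outcome on the
#' composite score `F Z w` (plus covariates); as the variances grow large it
#' approaches the unpenalized multiple regression on all foods.
#'
#' @param spec A [hier_spec()].
#' @param outcome Numeric outcome vector (one DASS subscale).
#' @param outcome_name Label carried into the fit.
#' @return Object of class `dii_fit`. Fixed-effect rows (covariates and the
#'   DII coefficient) carry GLS standard errors and Wald 95% intervals
#'   (estimate +/- 1.96 se); food/nutrient coefficient tables carry
#'   prediction standard errors from Henderson's equations. Food
#'   coefficients are reported both per standardized food column and
#'   back-transformed per input unit (grams/day).
#' @export
fit_hierarchical <- function(spec, outcome, outcome_name = "outcome") {
  assert_that(inherits(spec, "hier_spec"), "spec must come from hier_spec()")
  y <- as.numeric(outcome)
  assert_that(length(y) == nrow(spec$foods),
              "outcome length does not match the design")
  d <- hier_design(spec, y)
  pc <- d$pc
  J <- ncol(spec$foods); I <- ncol(spec$z)

  est_f <- identical(spec$tau2_food, "estimate")
  est_n <- identical(spec$tau2_nutrient, "estimate")
  evals <- 0L
  converged <- TRUE
  note <- NULL
  est_blocks <- list()
  if (est_f && est_n && spec$shared_tau2) {
    est_blocks <- list(seq_len(J + I))            # one common tau2
  } else {
    if (est_f) est_blocks <- c(est_blocks, list(seq_len(J)))
    if (est_n) est_blocks <- c(est_blocks, list(J + seq_len(I)))
  }

  if (est_f && est_n && spec$shared_tau2) {
    obj <- function(ll) {
      evals <<- evals + 1L
      reml_neg2(pc, rep(exp(ll), J + I))
    }
    op <- stats::optimize(obj, c(-30, 10), tol = spec$tolerance)
    lam2 <- rep(exp(op$minimum), 2)
    if (reml_neg2(pc, rep(0, J + I)) <= op$objective) lam2 <- c(0, 0)
    if (any(lam2 < 1e-10)) { lam2[lam2 < 1e-10] <- 0; note <- "tau2 at boundary" }
    lamvec <- c(rep(lam2[1], J), rep(lam2[2], I))
    sol <- hier_solve(pc, lamvec)
    s2 <- sol$rss / (pc$n - pc$p)
    tau2 <- lam2 * s2
  } else if (est_f && est_n) {
    eb <- estimate_tau2_eb(spec, y)
    evals <- eb$n_evaluations
    tau2 <- c(eb$tau2_food, eb$tau2_nutrient)
    s2 <- eb$residual_variance
    lamvec <- c(rep(tau2[1] / s2, J), rep(tau2[2] / s2, I))
    sol <- hier_solve(pc, lamvec)
    if (eb$boundary) note <- "tau2 at boundary"
  } else if (est_f || est_n) {
    # one level estimated, the other fixed in absolute terms: joint 2-D
    # search over (log tau2_free, log sigma2), non-profiled
    fixed_val <- if (est_f) spec$tau2_nutrient else spec$tau2_food
    obj <- function(par) {
      evals <<- evals + 1L
      t2 <- exp(par[1]); s2 <- exp(par[2])
      tf <- if (est_f) t2 else fixed_val
      tn <- if (est_n) t2 else fixed_val
      reml_neg2(pc, c(rep(tf / s2, J), rep(tn / s2, I)), s2)
    }
    op <- stats::optim(c(log(stats::var(y) / 10), log(stats::var(y))), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = spec$max_iterations * 5,
                                      reltol = spec$tolerance))
    t2_free <- exp(op$par[1]); s2 <- exp(op$par[2])
    if (t2_free < 1e-10 * s2) { t2_free <- 0; note <- "tau2 at boundary" }
    tau2 <- c(if (est_f) t2_free else fixed_val,
              if (est_n) t2_free else fixed_val)
    lamvec <- c(rep(tau2[1] / s2, J), rep(tau2[2] / s2, I))
    sol <- hier_solve(pc, lamvec)
  } else {
    tau2 <- c(spec$tau2_food, spec$tau2_nutrient)
    if (is.null(spec$sigma2)) {
      # fixed absolute tau2, residual variance estimated: 1-D REML in sigma2
      obj <- function(ls2) {
        evals <<- evals + 1L
        s2 <- exp(ls2)
        reml_neg2(pc, c(rep(tau2[1] / s2, J), rep(tau2[2] / s2, I)), s2)
      }
      op <- stats::optimize(obj, log(stats::var(y)) + c(-12, 6),
                            tol = spec$tolerance)
      s2 <- exp(op$minimum)
    } else {
      s2 <- spec$sigma2
    }
    lamvec <- c(rep(tau2[1] / s2, J), rep(tau2[2] / s2, I))
    sol <- hier_solve(pc, lamvec)
    if (length(sol$act) == 0 && is.null(spec$sigma2))
      s2 <- sol$rss / (pc$n - pc$p)
  }
  if (evals >= spec$max_iterations * 25) {
    converged <- FALSE
    note <- paste(c(note, "iteration budget exhausted"), collapse = "; ")
  }

  # Final estimates and BLUPs from Henderson's mixed-model equations
  #   [X'X  X'U ] [b]   [X'y]
  #   [U'X  U'U + Lambda^{-1}] [u] = [U'y]
  # solved jointly: numerically stable even for very large tau2, where the
  # Woodbury subtraction used inside the REML objective loses precision.
  p <- pc$p
  act <- sol$act
  Cmat <- rbind(cbind(pc$XtX, t(pc$B[act, , drop = FALSE])),
                cbind(pc$B[act, , drop = FALSE],
                      pc$A[act, act, drop = FALSE] +
                        diag(1 / lamvec[act], nrow = length(act))))
  rhs <- c(pc$Xty, pc$uy[act])
  Cinv <- solve(Cmat)
  bu <- drop(Cinv %*% rhs)
  b <- bu[seq_len(p)]
  uhat <- numeric(pc$q)
  uhat[act] <- bu[p + seq_along(act)]
  se_b <- sqrt(pmax(diag(Cinv)[seq_len(p)] * s2, 0))
  se_adjusted <- FALSE
  df_b <- rep(Inf, p)
  if (length(est_blocks)) {
    kr <- kr_adjusted_cov(pc, lamvec, s2, est_blocks,
                          sigma_free = is.null(spec$sigma2))
    if (kr$adjusted) {
      se_b <- sqrt(pmax(diag(kr$cov), 0))
      df_b <- kr$df
      se_adjusted <- TRUE
    }
  }
  names(se_b) <- names(b) <- colnames(d$X)

  delta_hat <- uhat[seq_len(J)]
  theta_hat <- uhat[J + seq_len(I)]
  gamma <- unname(b["dii"])
  pi_hat <- spec$w * gamma + theta_hat
  beta_std <- drop(spec$z %*% pi_hat) + delta_hat

  # Prediction covariance of (b, u) = s2 * Cinv, for the standard errors of
  # the derived food/nutrient coefficients.
  se_beta <- se_pi <- NULL
  if (!is.null(Cinv)) {
    # beta_j = (Z w)_j gamma + delta_j + (Z theta)_j ; pi_i = w_i gamma + theta_i
    gcol <- which(colnames(d$X) == "dii")
    Tb <- matrix(0, J, p + length(act))
    Tp <- matrix(0, I, p + length(act))
    Tb[, gcol] <- drop(spec$z %*% spec$w)
    Tp[, gcol] <- spec$w
    pos <- match(seq_len(J), act)
    hasd <- which(!is.na(pos))
    Tb[cbind(hasd, p + pos[hasd])] <- 1
    post <- match(J + seq_len(I), act)
    hast <- which(!is.na(post))
    Tp[cbind(hast, p + post[hast])] <- 1
    if (length(hast)) Tb[, p + post[hast]] <- Tb[, p + post[hast]] +
        spec$z[, hast, drop = FALSE]
    se_beta <- sqrt(pmax(rowSums((Tb %*% Cinv) * Tb) * s2, 0))
    se_pi <- sqrt(pmax(rowSums((Tp %*% Cinv) * Tp) * s2, 0))
  }

  # With estimated variance components the interval uses a t quantile at the
  # Satterthwaite df (the se tracks tau2-hat and is noisy; a plain 1.96
  # normal quantile undercovers). With fixed components se is exact and the
  # interval is the plain Wald one.
  crit <- ifelse(is.finite(df_b), stats::qt(0.975, df_b), Z95)
  tval <- ifelse(se_b > 0, b / se_b, sign(b) * Inf)
  pval <- ifelse(is.finite(df_b), 2 * stats::pt(-abs(tval), df_b),
                 2 * stats::pnorm(-abs(tval)))
  coefficients <- data.frame(term = colnames(d$X), estimate = unname(b),
                             se = unname(se_b),
                             df = unname(df_b),
                             lower = unname(b - crit * se_b),
                             upper = unname(b + crit * se_b),
                             p = unname(pval),
                             stringsAsFactors = FALSE)

  food_scale <- spec$scale_info$food_scale
  foods_tab <- data.frame(food = colnames(spec$foods),
                          beta_std = beta_std,
                          beta = beta_std / food_scale,
                          stringsAsFactors = FALSE)
  if (!is.null(se_beta)) {
    foods_tab$se_std <- se_beta
    foods_tab$se <- se_beta / food_scale
  }
  nutrients_tab <- data.frame(nutrient = colnames(spec$z), pi = pi_hat,
                              stringsAsFactors = FALSE)
  if (!is.null(se_pi)) nutrients_tab$se <- se_pi

  drow <- which(coefficients$term == "dii")
  structure(list(model = "hierarchical", outcome = outcome_name,
                 coefficients = coefficients, gamma = gamma,
                 se_gamma = unname(se_b["dii"]),
                 ci_gamma = c(lower = coefficients$lower[drow],
                              upper = coefficients$upper[drow]),
                 p_gamma = coefficients$p[drow],
                 df_gamma = coefficients$df[drow],
                 foods = foods_tab, nutrients = nutrients_tab,
                 delta_hat = delta_hat, theta_hat = theta_hat,
                 tau2 = c(food = unname(tau2[1]), nutrient = unname(tau2[2])),
                 residual_variance = s2,
                 dii_sd = stats::sd(d$composite),
                 composite = d$composite, se_adjusted = se_adjusted,
                 converged = converged, n_iterations = evals, note = note,
                 n = pc$n), class = "dii_fit")
}

#' Simple linear regression of an outcome on the DII
#'
#' @param outcome,dii Equal-length numeric vectors, n >= 3; `dii` must not be
#'   constant.
#' @param outcome_name Label carried into the fit.
#' @return A `dii_fit` with the OLS intercept and slope, Wald 95% intervals.
#' @export
fit_simple <- function(outcome, dii, outcome_name = "outcome") {
  y <- as.numeric(outcome); x <- as.numeric(dii)
  assert_that(length(y) == length(x), "outcome and dii lengths differ")
  assert_that(length(y) >= 3, "need at least 3 observations")
  sxx <- sum((x - mean(x))^2)
  assert_that(sxx > 0, "DII is constant; the simple model is undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (length(y) - 2)
  se <- c(sqrt(s2 * (1 / length(y) + mean(x)^2 / sxx)), sqrt(s2 / sxx))
  est <- c(intercept, slope)
  ci <- wald_ci(est, se)
  structure(list(model = "simple", outcome = outcome_name,
                 coefficients = data.frame(
                   term = c("(Intercept)", "dii"), estimate = est, se = se,
                   lower = ci[, "lower"], upper = ci[, "upper"],
                   p = wald_p(est, se), stringsAsFactors = FALSE),
                 gamma = slope, se_gamma = se[2],
                 ci_gamma = c(lower = unname(ci[2, "lower"]),
                              upper = unname(ci[2, "upper"])),
                 p_gamma = wald_p(est, se)[2],
                 residual_variance = s2, dii_sd = stats::sd(x),
                 converged = TRUE, n = length(y)), class = "dii_fit")
}

#' Multiple linear regression with food and nutrient adjustment
#'
#' OLS of the outcome on the DII plus covariates, foods and nutrients
#' jointly — the conventional way of "adjusting for everything", which with
#' many correlated exposures inflates the DII standard error. Exactly aliased
#' columns are dropped by pivoted QR (relative tolerance 1e-10), later
#' columns first, so derived nutrient columns (exact linear combinations of
#' the foods) give way to the foods themselves; dropped names are recorded.
#'
#' @param outcome Numeric outcome vector.
#' @param dii Numeric DII vector, or NULL to omit.
#' @param covariates,nutrients,foods Optional numeric matrices/data.frames.
#' @param outcome_name Label carried into the fit.
#' @return A `dii_fit`; `dropped` lists removed columns.
#' @export
fit_multiple <- function(outcome, dii, covariates = NULL, nutrients = NULL,
                         foods = NULL, outcome_name = "outcome") {
  y <- as.numeric(outcome)
  blocks <- list(`(Intercept)` = matrix(1, length(y), 1,
                                        dimnames = list(NULL, "(Intercept)")))
  add <- function(blocks, m, prefix) {
    if (is.null(m)) return(blocks)
    m <- as.matrix(m)
    assert_that(nrow(m) == length(y), "%s block has wrong row count", prefix)
    if (is.null(colnames(m)))
      colnames(m) <- sprintf("%s_%d", prefix, seq_len(ncol(m)))
    blocks[[prefix]] <- m
    blocks
  }
  if (!is.null(dii)) blocks <- add(blocks, cbind(dii = as.numeric(dii)), "dii")
  blocks <- add(blocks, covariates, "covariate")
  blocks <- add(blocks, foods, "food")
  blocks <- add(blocks, nutrients, "nutrient")
  X <- do.call(cbind, unname(blocks))

  qrx <- qr(X, tol = 1e-10)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  Xk <- X[, keep, drop = FALSE]
  assert_that(length(y) > ncol(Xk),
              paste("n <= number of retained columns; the conventional",
                    "multiple model is saturated - use the hierarchical",
                    "model instead"))
  fit <- stats::lm.fit(Xk, y)
  b <- fit$coefficients
  res <- fit$residuals
  s2 <- sum(res^2) / (length(y) - ncol(Xk))
  XtXi <- chol2inv(qr.R(fit$qr))[order(fit$qr$pivot), order(fit$qr$pivot)]
  se <- sqrt(pmax(diag(XtXi) * s2, 0))
  ci <- wald_ci(b, se)
  coefficients <- data.frame(term = colnames(Xk), estimate = unname(b),
                             se = unname(se),
                             lower = unname(ci[, "lower"]),
                             upper = unname(ci[, "upper"]),
                             p = unname(wald_p(b, se)),
                             stringsAsFactors = FALSE)
  drow <- which(coefficients$term == "dii")
  gamma <- if (length(drow)) coefficients$estimate[drow] else NA_real_
  se_g <- if (length(drow)) coefficients$se[drow] else NA_real_
  ci_g <- if (length(drow))
    c(lower = coefficients$lower[drow], upper = coefficients$upper[drow])
  else c(lower = NA_real_, upper = NA_real_)
  p_g <- if (length(drow)) coefficients$p[drow] else NA_real_
  structure(list(model = "multiple", outcome = outcome_name,
                 coefficients = coefficients, gamma = gamma, se_gamma = se_g,
                 ci_gamma = ci_g, p_gamma = p_g,
                 dropped = dropped, residual_variance = s2,
                 dii_sd = if (!is.null(dii)) stats::sd(as.numeric(dii)) else NA_real_,
                 converged = TRUE, n = length(y)), class = "dii_fit")
}

#' @export
print.dii_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%s), n = %d\n", x$model, x$outcome, x$n))
  if (!is.null(x$gamma) && is.finite(x$gamma)) {
    cat(sprintf("  DII coefficient: %.4f (se %.4f, 95%% CI %.4f to %.4f)\n",
                x$gamma, x$se_gamma, x$ci_gamma["lower"],
                x$ci_gamma["upper"]))
  }
  if (!is.null(x$tau2))
    cat(sprintf("  tau2 (food, nutrient): %.5f, %.5f; residual %.4f\n",
                x$tau2["food"], x$tau2["nutrient"], x$residual_variance))
  if (!is.null(x$dropped) && length(x$dropped))
    cat("  dropped aliased columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
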