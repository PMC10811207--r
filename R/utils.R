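## Internal helpers shared across modules.

#' diinest: DII scoring and hierarchical models for nested dietary exposures
#'
#' @keywords internal
"_PACKAGE"

# Deterministic child seeds: every stage of a run derives its own stream from
# the single user-facing seed. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483587L + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Wald normal quantile used throughout for 95% intervals.
Z95 <- 1.96

wald_ci <- function(estimate, se) {
  cbind(lower = estimate - Z95 * se, upper = estimate + Z95 * se)
}

wald_p <- function(estimate, se) {
  z <- ifelse(se > 0, abs(estimate) / se, Inf)
  2 * stats::pnorm(-z)
}

#' Display convention for p-values: three decimals with a "<0.001" floor
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
fmt_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Percentage of a count out of a total, rounded for display
#' @param count,total Counts.
#' @param digits Decimals (default 1), e.g. `pct(1362, 3501)` is 38.9.
#' @return Numeric percentage.
#' @export
pct <- function(count, total, digits = 1) {
  assert_that(total > 0, "pct(): total must be positive")
  round(100 * count / total, digits)
}

# Column standardization (mean 0, sd 1, denominator n-1). Constant columns are
# an error: a constant exposure carries no information and breaks the bridges.
standardize_columns <- function(m, label = "design") {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  bad <- which(!is.finite(sd) | sd <= 0)
  if (length(bad)) {
    stopf("constant or degenerate column(s) in %s: %s", label,
          paste(utils::head(colnames(m)[bad], 5), collapse = ", "))
  }
  list(x = sweep(sweep(m, 2, mu, "-"), 2, sd, "/"), center = mu, scale = sd)
}
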