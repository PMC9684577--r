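# Sample-size computation for the paired (one-sample) t-test, using the
# exact noncentral t distribution rather than the normal shortcut.

#' Power of a two-sided paired t-test
#'
#' Exact power at sample size `n` for standardized effect `d`
#' (mean paired difference divided by the within-subject SD of the
#' differences): the test statistic follows a noncentral t distribution
#' with `n - 1` degrees of freedom and noncentrality `d * sqrt(n)`.
#'
#' @param n Number of pairs (n >= 2).
#' @param d Standardized effect size, `delta / sd`.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  if (any(n < 2)) {
    .tc_stop("tonocorr_usage_error", "power_paired_t needs n >= 2")
  }
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- abs(d) * sqrt(n)
  (1 - stats::pt(tc, df, ncp = ncp)) + stats::pt(-tc, df, ncp = ncp)
}

#' Smallest sample size attaining a target power for the paired t-test
#'
#' Finds the smallest integer `n >= 2` such that a two-sided paired
#' t-test with significance level `alpha` attains power at least `power`
#' for standardized effect `d = delta / sd`, by exact noncentral-t
#' iteration: the search starts at the normal-approximation seed
#' `((z_{1-alpha/2} + z_{power}) / d)^2`, steps down while the target is
#' still met, and up until it is.
#'
#' @param delta Mean paired difference (mmHg). May be omitted if `d` is
#'   given directly.
#' @param sd Within-subject SD of the differences (mmHg).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param d Standardized effect size; defaults to `delta / sd`.
#' @param n_max Cap on the search (default 1e6); exceeding it raises an
#'   error rather than looping forever on a negligible effect.
#' @return A list of class `power_result`: `n`, `achieved_power`,
#'   `power_at_n_minus_1`, `d`, `alpha`, `power_target`.
#' @examples
#' required_n(delta = 0.5, sd = 1.5)  # n = 73
#' @export
required_n <- function(delta = NULL, sd = NULL, alpha = 0.05, power = 0.80,
                       d = NULL, n_max = 1e6) {
  if (is.null(d)) {
    if (is.null(delta) || is.null(sd)) {
      .tc_stop("tonocorr_usage_error", "supply either d or both delta and sd")
    }
    if (sd <= 0) .tc_stop("tonocorr_usage_error", "sd must be positive")
    if (delta == 0) .tc_stop("tonocorr_usage_error", "delta must be nonzero")
    d <- delta / sd
  }
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1)) {
    .tc_stop("tonocorr_usage_error", "alpha and power must lie in (0, 1)")
  }
  d <- abs(d)
  seed_n <- ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / d)^2
  n <- max(2, ceiling(seed_n))
  if (n > n_max) {
    .tc_stop("tonocorr_cap_error",
             "required sample size exceeds cap n_max = %g (effect too small)", n_max)
  }
  while (n > 2 && power_paired_t(n - 1, d, alpha) >= power) n <- n - 1
  while (power_paired_t(n, d, alpha) < power) {
    n <- n + 1
    if (n > n_max) {
      .tc_stop("tonocorr_cap_error",
               "required sample size exceeds cap n_max = %g (effect too small)", n_max)
    }
  }
  structure(list(
    n = as.integer(n),
    achieved_power = power_paired_t(n, d, alpha),
    power_at_n_minus_1 = if (n > 2) power_paired_t(n - 1, d, alpha) else NA_real_,
    d = d, alpha = alpha, power_target = power
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Paired t-test sample size: n = %d (d = %.4f, alpha = %g two-sided, target power = %g)\n",
              x$n, x$d, x$alpha, x$power_target))
  cat(sprintf("  power at n: %.4f | at n - 1: %s\n", x$achieved_power,
              if (is.na(x$power_at_n_minus_1)) "-" else sprintf("%.4f", x$power_at_n_minus_1)))
  invisible(x)
}
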