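# Paired method-comparison statistics: signed and absolute differences with
# paired t-tests, Bland-Altman limits of agreement with fixed- and
# proportional-bias detection, and Monte-Carlo Lilliefors normality.
#
# Conventions: differences are x - y (first method minus second); sample SD
# uses the n-1 denominator; limits of agreement use mean +/- k*SD with
# k = 2 by default.

.check_paired <- function(x, y) {
  if (length(x) != length(y)) {
    .tc_stop("tonocorr_alignment_error",
             "paired series have different lengths (%d vs %d)",
             length(x), length(y))
  }
  if (length(x) < 2) {
    .tc_stop("tonocorr_insufficient_data_error",
             "need at least 2 pairs, got %d", length(x))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    .tc_stop("tonocorr_validation_error", "paired series contain non-finite values")
  }
  invisible(TRUE)
}

#' Paired comparison of two aligned measurement series
#'
#' Computes signed-difference statistics (`mean_diff`, `sd_diff`, paired
#' t-test) and absolute-difference statistics (`mean_absdiff`,
#' `sd_absdiff`) for `x - y`. The paired t statistic is
#' `mean_diff / (sd_diff / sqrt(n))` with a two-sided p-value from the t
#' distribution on `n - 1` degrees of freedom. A zero-variance difference
#' series yields `t = 0, p = 1` when the mean is zero and `t = Inf, p = 0`
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length, aligned by record (mmHg).
#' @param label Label for reports.
#' @return A `paired_comparison` object (list).
#' @export
paired_compare <- function(x, y, label = "x - y") {
  .check_paired(x, y)
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s > 0) {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  } else {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  }
  structure(list(
    label = label, n = n,
    mean_diff = m, sd_diff = s,
    mean_absdiff = mean(abs(d)), sd_absdiff = stats::sd(abs(d)),
    t_stat = t_stat, p_value = p
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison: %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  signed   %.2f +/- %.2f mmHg  (t = %.3f, p = %.3g)\n",
              x$mean_diff, x$sd_diff, x$t_stat, x$p_value))
  cat(sprintf("  absolute %.2f +/- %.2f mmHg\n", x$mean_absdiff, x$sd_absdiff))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Computes per-pair means `(x + y) / 2` and differences `x - y`, the mean
#' difference, and limits of agreement `mean_diff +/- k * sd_diff`.
#' Fixed bias is flagged when zero lies outside the limits of agreement.
#' Proportional bias is assessed by the ordinary-least-squares slope of
#' the differences on the pairwise means, with a two-sided t-test on the
#' slope at level `alpha`.
#'
#' @param x,y Numeric vectors of equal length (mmHg).
#' @param k Limits-of-agreement multiplier (default 2, i.e. mean +/- 2 SD).
#' @param alpha Significance level for the proportional-bias slope test.
#' @param label Label for reports.
#' @return A `bland_altman` object: `mean_diff`, `sd_diff`, `k`,
#'   `loa_low`, `loa_high`, `fixed_bias`, `prop_slope`, `prop_p`,
#'   `prop_bias`, `prop_test_skipped`, and a data.frame `points` of
#'   (mean, difference) coordinates for plotting or export.
#' @export
bland_altman <- function(x, y, k = 2, alpha = 0.05, label = "x vs y") {
  .check_paired(x, y)
  d <- x - y
  avg <- (x + y) / 2
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - k * s, m + k * s)
  fixed <- (0 < loa[1]) || (0 > loa[2])
  # the slope test needs spread in the means and in the differences
  skipped <- stats::var(avg) == 0 || stats::var(d) == 0
  if (!skipped && length(d) >= 3) {
    # OLS of difference on pairwise mean, two-sided t-test on the slope.
    # Computed directly (not via summary.lm) so an exactly collinear
    # difference series gives se = 0 -> p = 0 without spurious warnings.
    n <- length(d)
    sxx <- sum((avg - mean(avg))^2)
    slope <- sum((avg - mean(avg)) * (d - mean(d))) / sxx
    rss <- sum((d - mean(d) - slope * (avg - mean(avg)))^2)
    se <- sqrt(rss / (n - 2) / sxx)
    if (se > 0) {
      prop_p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
    } else {
      prop_p <- if (slope == 0) 1 else 0
    }
  } else {
    skipped <- TRUE
    slope <- if (stats::var(d) == 0) 0 else NA_real_
    prop_p <- NA_real_
  }
  structure(list(
    label = label, n = length(d),
    mean_diff = m, sd_diff = s, k = k,
    loa_low = loa[1], loa_high = loa[2],
    fixed_bias = fixed,
    prop_slope = slope, prop_p = prop_p,
    prop_bias = isTRUE(!is.na(prop_p) && prop_p < alpha),
    prop_test_skipped = skipped, alpha = alpha,
    points = data.frame(mean = avg, difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  mean difference %.2f mmHg, LoA [%.2f, %.2f] (k = %g)\n",
              x$mean_diff, x$loa_low, x$loa_high, x$k))
  cat(sprintf("  fixed bias: %s | proportional bias: %s (slope %.3f, p = %.3g)\n",
              x$fixed_bias,
              if (x$prop_test_skipped) "not tested" else x$prop_bias,
              x$prop_slope, x$prop_p))
  invisible(x)
}

#' Monte-Carlo Lilliefors test of normality
#'
#' Kolmogorov-Smirnov distance of the sample against a normal distribution
#' with mean and SD estimated from the sample, with the null distribution
#' of the statistic obtained by Monte-Carlo: `n_mc` standard-normal samples
#' of the same size are drawn and the statistic recomputed with parameters
#' re-estimated each time (the Lilliefors construction). The p-value is
#' `(1 + #{D_mc >= D}) / (n_mc + 1)`.
#'
#' @param x Numeric sample, at least 5 observations with positive variance.
#' @param n_mc Number of Monte-Carlo replicates (default 10000).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return A `normality_result`: `statistic`, `p_value`, `method`, `n_mc`.
#' @export
ks_normality <- function(x, n_mc = 10000, seed = 1) {
  if (length(x) < 5) {
    .tc_stop("tonocorr_insufficient_data_error",
             "normality test needs n >= 5, got %d", length(x))
  }
  if (stats::sd(x) == 0) {
    .tc_stop("tonocorr_validation_error",
             "normality test is degenerate for a constant series")
  }
  n <- length(x)
  lillie_stat <- function(z) {
    z <- sort((z - mean(z)) / stats::sd(z))
    p <- stats::pnorm(z)
    i <- seq_len(length(z))
    max(max(i / n - p), max(p - (i - 1) / n))
  }
  d_obs <- lillie_stat(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  d_mc <- vapply(seq_len(n_mc), function(i) lillie_stat(stats::rnorm(n)), 0)
  p <- (1 + sum(d_mc >= d_obs)) / (n_mc + 1)
  structure(list(statistic = d_obs, p_value = p,
                 method = "Monte-Carlo Lilliefors (Kolmogorov-Smirnov)",
                 n = n, n_mc = n_mc, seed = seed),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("%s: D = %.4f, p = %.4f (n = %d, %d MC replicates)\n",
              x$method, x$statistic, x$p_value, x$n, x$n_mc))
  invisible(x)
}

#' Did a correction improve agreement? Paired test on absolute errors
#'
#' Given the per-eye absolute differences |DCT - GAT| before and after a
#' correction, computes paired statistics of
#' `|d_corrected| - |d_uncorrected|`: a negative mean indicates the
#' correction moved GAT closer to DCT on average.
#'
#' @param diff_uncorrected Per-eye differences (signed or absolute) before
#'   correction; absolute values are taken internally.
#' @param diff_corrected Per-eye differences after correction, aligned.
#' @param label Label for reports.
#' @return A `paired_comparison` of the absolute errors
#'   (corrected minus uncorrected).
#' @export
compare_correction_effect <- function(diff_uncorrected, diff_corrected,
                                      label = "correction effect") {
  .check_paired(diff_uncorrected, diff_corrected)
  paired_compare(abs(diff_corrected), abs(diff_uncorrected), label = label)
}
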