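# Small statistical primitives: likelihood-ratio test, Holm step-down
# adjustment, power / sample-size iteration, proportion boundary
# compression.

#' Likelihood-ratio test between two nested fits
#'
#' @param loglik0,loglik1 Log-likelihoods of the reduced and full model.
#' @param df0,df1 Their parameter counts (`df1 > df0`).
#' @param tol Tolerance for a slightly negative statistic from numerical
#'   optimisation; such values are clamped to zero.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' lr_test(-100, -98.08, 3, 4)
lr_test <- function(loglik0, loglik1, df0, df1, tol = 1e-6) {
  if (df1 <= df0) abort_bad_arg("`df1` must exceed `df0` (nested models).")
  stat <- 2 * (loglik1 - loglik0)
  if (stat < -tol) {
    abort_bad_arg("Negative likelihood-ratio statistic: models not nested or fit failed.")
  }
  stat <- max(stat, 0)
  df <- df1 - df0
  tibble::tibble(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity, caps at 1 and restores the input
#' order. Controls the family-wise error rate at the nominal level.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort_bad_arg("All p-values must lie in (0, 1].")
  }
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * (m - seq_len(m) + 1)
  stepped <- pmin(cummax(stepped), 1)
  out <- numeric(m)
  out[ord] <- stepped
  out
}

#' Sample size per group for a two-sample t-test
#'
#' Smallest equal group size `n` for which the (two-sided by default)
#' two-sample t-test at significance `alpha` reaches the target power for a
#' raw mean difference `delta` with common SD `sd`, by direct iteration of
#' the noncentral-t power function.
#'
#' @param delta Raw between-group difference.
#' @param sd Common standard deviation.
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param two_sided Two-sided test?
#' @return Integer group size.
#' @export
#' @examples
#' power_sample_size(0.2, 0.2, power = 0.8, alpha = 0.05) # 17
power_sample_size <- function(delta, sd, power = 0.8, alpha = 0.05,
                              two_sided = TRUE) {
  stop_if_not_scalar_number(delta, "delta", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(sd, "sd", min = 0, strict_min = TRUE)
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    abort_bad_arg("`power` and `alpha` must lie in (0, 1).")
  }
  if (power <= alpha) abort_bad_arg("Target power must exceed alpha.")
  d <- delta / sd
  for (n in 2:1e6) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    pw <- if (two_sided) {
      crit <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
    } else {
      1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
    }
    if (pw >= power) return(as.integer(n))
  }
  abort_bad_arg("No attainable sample size below 1e6.")
}

#' Compress proportions away from the boundary
#'
#' The Smithson-Verkuilen transformation `(y * (n - 1) + 0.5) / n`, mapping
#' observed proportions in \[0, 1\] into (0, 1) so a beta likelihood is
#' well-defined. `n` defaults to the number of observations.
#'
#' @param y Proportions in \[0, 1\].
#' @param n Compression denominator.
#' @return Compressed proportions strictly inside (0, 1).
#' @export
compress_proportions <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    abort_bad_arg("Proportions must lie in [0, 1].")
  }
  (y * (n - 1) + 0.5) / n
}
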