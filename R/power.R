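# Stand-alone study-design power utilities: the Fisher-z sample size
# for detecting a correlation, and the minimal number of positives for
# significant AUC detection with Hanley-McNeil variances.

#' Sample size to detect a correlation (Fisher z)
#'
#' `N = ceiling(((z_{1-alpha/2} + z_{power}) / C)^2 + 3)` with
#' `C = 0.5 * ln((1 + r) / (1 - r))`, assuming bivariate normality.
#'
#' @param r Target correlation, in `(0, 1)`.
#' @param alpha Two-tailed type-I error rate (default 0.05).
#' @param power Desired power (default 0.8).
#' @return Integer sample size.
#' @export
fisher_z_sample_size <- function(r, alpha = 0.05, power = 0.8) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  C <- 0.5 * log((1 + r) / (1 - r))
  as.integer(ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) / C)^2 + 3))
}

# Hanley-McNeil variance of an empirical AUC with m positives and n
# negatives: Q1 = A/(2-A), Q2 = 2A^2/(1+A).
#' @noRd
hanley_mcneil_var <- function(A, m, n) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  (A * (1 - A) + (m - 1) * (Q1 - A^2) + (n - 1) * (Q2 - A^2)) / (m * n)
}

#' Minimal positives for significant AUC detection
#'
#' Smallest number of positive samples m (out of `total_n`) such that a
#' two-tailed test of the empirical AUC against the null value 0.5, with
#' Hanley-McNeil variances under null and alternative, attains the
#' requested power at alternative AUC `auc_alt`.
#'
#' @param total_n Total sample size (> 2).
#' @param auc_alt Alternative AUC, in `(0.5, 1]`.
#' @param alpha Two-tailed type-I error rate (default 0.05).
#' @param power Desired power (default 0.8).
#' @return Integer minimal number of positives.
#' @export
auc_detection_min_positives <- function(total_n, auc_alt, alpha = 0.05,
                                        power = 0.8) {
  stopifnot(total_n > 2, alpha > 0, alpha < 1, power > 0, power < 1)
  if (auc_alt <= 0.5 || auc_alt > 1)
    stop("alternative AUC must lie in (0.5, 1]")
  za <- qnorm(1 - alpha / 2)
  for (m in 2:(total_n - 2)) {
    n <- total_n - m
    v0 <- hanley_mcneil_var(0.5, m, n)
    v1 <- hanley_mcneil_var(auc_alt, m, n)
    attained <- pnorm((auc_alt - 0.5 - za * sqrt(v0)) / sqrt(v1))
    if (attained >= power) return(as.integer(m))
  }
  stop("requested power unreachable within total_n")
}
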