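# Analytic power for MR with a binary outcome (normal-approximation
# method of the mRnd calculator).
#
# With total sample size N, case fraction K, instrument R^2 on the
# exposure, and hypothesized causal odds ratio OR per SD of exposure, the
# causal effect is mapped to the risk-difference scale,
#   b = K * (OR / (1 + K*(OR - 1)) - 1),   v = K*(1 - K) - b^2,
# giving a chi-squared(1) test with non-centrality N * R^2 * b^2 / v.

#' Analytic MR power for a binary outcome
#'
#' Power of a two-sided Wald test of the causal effect in an MR analysis
#' with a case-control (binary) outcome, given the fraction of exposure
#' variance explained by the instrument. The hypothesized effect is an odds
#' ratio per standard deviation of the exposure. Power is monotone
#' increasing in total sample size, in `r2`, and in the distance of
#' `or_per_sd` from 1, and equals `alpha` at `or_per_sd = 1`. It is
#' invariant under swapping the case/control labels (`n_cases` with
#' `n_controls` and `or_per_sd` with `1/or_per_sd`).
#'
#' @param n_cases,n_controls Case and control counts (>= 1).
#' @param r2 Fraction of exposure variance explained by the instrument,
#'   in (0, 1) — e.g. 0.0284 for the six-variant 25-OHD score.
#' @param or_per_sd Hypothesized causal odds ratio per SD of exposure (> 0).
#'   Vectorized.
#' @param alpha Two-sided type-I error (default 0.05).
#' @return Power in `[0, 1]` (vector if `or_per_sd` is a vector).
#' @examples
#' mr_power_binary(9940, 22848, r2 = 0.0284, or_per_sd = 0.83)
#' @export
mr_power_binary <- function(n_cases, n_controls, r2, or_per_sd,
                            alpha = 0.05) {
  if (length(n_cases) != 1L || length(n_controls) != 1L ||
      n_cases < 1 || n_controls < 1) {
    stop("n_cases and n_controls must be single counts >= 1")
  }
  if (length(r2) != 1L || !is.finite(r2) || r2 <= 0 || r2 >= 1) {
    stop("r2 must be a single value in (0, 1)")
  }
  if (any(!is.finite(or_per_sd)) || any(or_per_sd <= 0)) {
    stop("or_per_sd must be positive")
  }
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  n <- n_cases + n_controls
  k <- n_cases / n
  b <- k * (or_per_sd / (1 + k * (or_per_sd - 1)) - 1)
  v <- k * (1 - k) - b^2
  ncp <- n * r2 * b^2 / v
  stats::pchisq(stats::qchisq(1 - alpha, df = 1L), df = 1L, ncp = ncp,
                lower.tail = FALSE)
}

#' Power grid over effect sizes and instrument strength
#'
#' Cartesian grid of [mr_power_binary()] over hypothesized odds ratios and
#' instrument R-squared values, at fixed case/control counts — the standard
#' supplementary power table for an MR study design.
#'
#' @inheritParams mr_power_binary
#' @param or_values Odds ratios per SD (non-empty).
#' @param r2_values Instrument R-squared values (non-empty).
#' @return A `data.frame` with columns `or_per_sd`, `r2`, `power`.
#' @export
mr_power_grid <- function(n_cases, n_controls, or_values, r2_values,
                          alpha = 0.05) {
  if (!length(or_values) || !length(r2_values)) {
    stop("or_values and r2_values must be non-empty")
  }
  grid <- expand.grid(or_per_sd = or_values, r2 = r2_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$power <- mapply(function(or, r2) {
    mr_power_binary(n_cases, n_controls, r2, or, alpha)
  }, grid$or_per_sd, grid$r2)
  grid
}
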