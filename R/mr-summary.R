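# Summary-statistics (two-sample) MR estimators.
#
# Notation: for variant k, x_k is the per-allele effect on the exposure,
# y_k the per-allele log-odds effect on the outcome, s_k the standard error
# of y_k. All estimators act on harmonized inputs (x_k > 0).

mr_result_row <- function(method, beta, se, n_variants,
                          q_stat = NA_real_, p_het = NA_real_,
                          intercept = NA_real_, intercept_se = NA_real_,
                          intercept_p = NA_real_) {
  data.frame(
    method = method,
    beta = beta,
    se = se,
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    n_variants = n_variants,
    q_stat = q_stat,
    p_het = p_het,
    intercept = intercept,
    intercept_se = intercept_se,
    intercept_p = intercept_p,
    stringsAsFactors = FALSE
  )
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-variant Wald ratios with inverse-variance weights:
#' \deqn{\hat\beta = \frac{\sum_k x_k y_k s_k^{-2}}{\sum_k x_k^2 s_k^{-2}},
#'   \qquad se(\hat\beta) = \sqrt{1 / \textstyle\sum_k x_k^2 s_k^{-2}},}
#' equivalent to weighted least squares of the outcome effects on the
#' exposure effects through the origin with weights \eqn{s_k^{-2}} and the
#' residual dispersion fixed at 1. Cochran's Q over the per-variant ratios
#' (weights \eqn{x_k^2/s_k^2}) quantifies heterogeneity; its p-value uses a
#' chi-squared distribution on `n - 1` degrees of freedom. Heterogeneity is
#' conventionally flagged at p < 0.10, causal estimates at p < 0.05.
#'
#' @param variants Harmonized summary-statistics `data.frame`.
#' @param weight_multiplier Optional per-variant weight down-weighting
#'   factors in `[0, 1]` (see [penalize_weights()]); default all 1.
#' @return A one-row `data.frame` (method, beta, se, or, ci_low, ci_high,
#'   p_value, n_variants, q_stat, p_het, intercept fields `NA`).
#' @export
mr_ivw <- function(variants, weight_multiplier = NULL) {
  validate_variants(variants)
  if (nrow(variants) < 1L) stop("mr_ivw requires at least one variant")
  x <- variants$beta_exposure
  y <- variants$beta_outcome
  w <- 1 / variants$se_outcome^2
  m <- check_multiplier(weight_multiplier, nrow(variants))
  beta <- sum(m * w * x * y) / sum(m * w * x^2)
  se <- sqrt(1 / sum(m * w * x^2))
  ratio <- y / x
  q <- sum(m * w * x^2 * (ratio - beta)^2)
  p_het <- if (nrow(variants) > 1L) {
    stats::pchisq(q, df = nrow(variants) - 1L, lower.tail = FALSE)
  } else {
    NA_real_
  }
  method <- if (is.null(weight_multiplier)) "ivw" else "penalized_ivw"
  mr_result_row(method, beta, se, nrow(variants), q_stat = q, p_het = p_het)
}

check_multiplier <- function(m, n) {
  if (is.null(m)) return(rep(1, n))
  if (length(m) != n || any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop("weight_multiplier must be ", n, " finite values in [0, 1]")
  }
  if (all(m == 0)) stop("all variant weights penalized to zero")
  m
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with a free intercept (weights \eqn{s_k^{-2}}). The slope is a causal
#' estimate that remains consistent under directional (unbalanced)
#' pleiotropy satisfying the InSIDE assumption; an intercept significantly
#' different from zero (p < 0.05) indicates unbalanced pleiotropy. Requires
#' harmonized input: the intercept test is only meaningful with all exposure
#' effects oriented positive.
#'
#' Standard errors use a multiplicative overdispersion parameter floored at
#' one, `sigma2 = max(1, Q_E / (k - 2))` with `Q_E` the weighted residual
#' sum of squares — the convention of the standard two-sample MR software.
#' Set `overdispersion = FALSE` for plain dispersion-1 errors.
#'
#' @inheritParams mr_ivw
#' @param overdispersion Apply the floored multiplicative residual scale
#'   (default `TRUE`).
#' @return A one-row `data.frame` with intercept fields populated.
#' @export
mr_egger <- function(variants, weight_multiplier = NULL,
                     overdispersion = TRUE) {
  validate_variants(variants)
  if (nrow(variants) < 2L) stop("mr_egger requires at least two variants")
  assert_harmonized(variants, "mr_egger")
  x <- variants$beta_exposure
  y <- variants$beta_outcome
  w <- 1 / variants$se_outcome^2
  m <- check_multiplier(weight_multiplier, nrow(variants))
  w <- w * m
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  # dispersion-1 covariance: (X' W X)^{-1}
  X <- cbind(1, x)
  xtwx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  q_e <- sum(w * stats::residuals(fit)^2)
  k <- nrow(variants)
  sigma2 <- if (k > 2L) {
    if (overdispersion) max(1, q_e / (k - 2L)) else 1
  } else {
    1  # saturated: two points, zero residual
  }
  se <- sqrt(diag(xtwx_inv) * sigma2)
  p_het <- if (k > 2L) {
    stats::pchisq(q_e, df = k - 2L, lower.tail = FALSE)
  } else {
    NA_real_
  }
  method <- if (is.null(weight_multiplier)) "egger" else "penalized_egger"
  mr_result_row(method, beta = cf[["x"]], se = se[2L], n_variants = k,
                q_stat = q_e, p_het = p_het,
                intercept = cf[["(Intercept)"]], intercept_se = se[1L],
                intercept_p = 2 * stats::pnorm(-abs(cf[["(Intercept)"]] / se[1L])))
}

# Cumulative-weight interpolated weighted median of per-variant ratios:
# normalize weights to sum 1, assign sorted ratio j the percentile position
# cumsum_j - w_j/2, interpolate linearly at 0.5.
weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - 0.5 * w
  if (p[1L] >= 0.5) return(b[1L])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  j <- max(which(p < 0.5))
  b[j] + (b[j + 1L] - b[j]) * (0.5 - p[j]) / (p[j + 1L] - p[j])
}

#' Median-based causal estimates
#'
#' The simple median uses equal weights over the per-variant Wald ratios;
#' the weighted median uses the inverse-variance weights
#' \eqn{x_k^2/s_k^2}. Both interpolate the 50th percentile of the
#' cumulative-weight distribution over the sorted ratios, and both are
#' consistent when (at least half the weight of) the variants are valid
#' instruments. The standard error comes from a parametric bootstrap:
#' each ratio is resampled from `Normal(ratio_k, ratio_se_k)` and the median
#' recomputed; the normal approximation with the bootstrap SE gives the CI
#' and p-value. Resampling is keyed to variant ids (draws are generated in
#' id order), so results are invariant to input row order under a fixed
#' seed.
#'
#' @inheritParams mr_ivw
#' @param weighting `"simple"` (equal weights) or `"weighted"`
#'   (inverse-variance weights).
#' @param n_boot Number of bootstrap resamples (default 10000; fewer than
#'   100 triggers a warning).
#' @param seed Integer seed for the bootstrap (required).
#' @return A one-row `data.frame`.
#' @export
mr_median <- function(variants, weighting = c("simple", "weighted"),
                      n_boot = 10000L, seed, weight_multiplier = NULL) {
  weighting <- match.arg(weighting)
  validate_variants(variants)
  if (nrow(variants) < 3L) stop("mr_median requires at least three variants")
  if (missing(seed)) stop("mr_median requires an explicit bootstrap seed")
  if (n_boot < 100L) warning("n_boot < 100 gives unstable bootstrap SEs")
  m <- check_multiplier(weight_multiplier, nrow(variants))
  rt <- wald_ratios(variants)
  wts <- if (weighting == "simple") rep(1, nrow(rt)) else rt$iv_weight
  wts <- wts * m
  beta <- weighted_median(rt$ratio, wts)

  o <- order(rt$variant_id)  # id-keyed draws: row-order invariant
  ro <- rt$ratio[o]
  so <- rt$ratio_se[o]
  wo <- wts[o]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  z <- matrix(stats::rnorm(length(ro) * n_boot), nrow = length(ro))
  draws <- ro + so * z
  est <- apply(draws, 2L, weighted_median, w = wo)
  se <- stats::sd(est)
  method <- paste0(if (!is.null(weight_multiplier)) "penalized_" else "",
                   weighting, "_median")
  mr_result_row(method, beta, se, nrow(variants))
}

#' Heterogeneity-based weight penalization
#'
#' Down-weights variants whose Wald ratio is inconsistent with a reference
#' causal estimate. Each variant's heterogeneity contribution
#' `q_k = iv_weight_k * (ratio_k - reference_beta)^2` is referred to a
#' chi-squared distribution on one degree of freedom; the weight multiplier
#' is `min(1, 20 * p_k)` with `p_k` the upper-tail probability. Variants
#' with `p_k >= 0.05` keep full weight; gross outliers are driven towards
#' zero weight.
#'
#' @inheritParams mr_ivw
#' @param reference_beta Causal estimate defining consistency; defaults to
#'   the unpenalized IVW estimate of the same set.
#' @return Numeric vector of per-variant multipliers in `[0, 1]`.
#' @export
penalize_weights <- function(variants, reference_beta = NULL) {
  validate_variants(variants)
  if (is.null(reference_beta)) reference_beta <- mr_ivw(variants)$beta
  rt <- wald_ratios(variants)
  q_k <- rt$iv_weight * (rt$ratio - reference_beta)^2
  p_k <- stats::pchisq(q_k, df = 1L, lower.tail = FALSE)
  pmin(1, 20 * p_k)
}

#' Penalized IVW, Egger, or weighted-median estimate
#'
#' Applies [penalize_weights()] (reference = the corresponding unpenalized
#' estimate) and refits the chosen estimator with the down-weighted
#' variants.
#'
#' @inheritParams mr_median
#' @param method One of `"ivw"`, `"egger"`, `"weighted_median"`.
#' @return A one-row `data.frame` (method labelled `penalized_*`).
#' @export
mr_penalized <- function(variants, method = c("ivw", "egger", "weighted_median"),
                         n_boot = 10000L, seed = NULL) {
  method <- match.arg(method)
  ref <- switch(method,
    ivw = mr_ivw(variants)$beta,
    egger = mr_egger(variants)$beta,
    weighted_median = mr_median(variants, "weighted", n_boot = n_boot,
                                seed = if (is.null(seed)) 1L else seed)$beta
  )
  m <- penalize_weights(variants, reference_beta = ref)
  switch(method,
    ivw = mr_ivw(variants, weight_multiplier = m),
    egger = mr_egger(variants, weight_multiplier = m),
    weighted_median = {
      if (is.null(seed)) stop("penalized weighted median requires a seed")
      mr_median(variants, "weighted", n_boot = n_boot, seed = seed,
                weight_multiplier = m)
    }
  )
}

#' Robust (MM-estimation) IVW and Egger estimates
#'
#' Refits the IVW (through-origin) or Egger (free-intercept) weighted
#' regression by MM-estimation with Tukey's biweight (95%-efficiency tuning
#' constant 4.685, convergence tolerance 1e-8, at most 200 iterations),
#' which bounds the influence of outlying variants.
#'
#' @inheritParams mr_ivw
#' @param method `"ivw"` or `"egger"`.
#' @return A one-row `data.frame` (method labelled `robust_*`). Intercept
#'   fields are populated for `"egger"`.
#' @export
mr_robust <- function(variants, method = c("ivw", "egger")) {
  method <- match.arg(method)
  validate_variants(variants)
  if (method == "egger") assert_harmonized(variants, "mr_robust(egger)")
  if (nrow(variants) < 2L) stop("mr_robust requires at least two variants")
  x <- variants$beta_exposure
  y <- variants$beta_outcome
  w <- 1 / variants$se_outcome^2
  # on an exact fit the MM scale estimate degenerates; the robust fit is
  # then the standard fit by definition
  std <- if (method == "ivw") mr_ivw(variants) else mr_egger(variants)
  fitted_std <- if (method == "ivw") std$beta * x else
    std$intercept + std$beta * x
  if (sum(w * (y - fitted_std)^2) < 1e-16 * sum(w * y^2) + 1e-300) {
    std$method <- paste0("robust_", method)
    return(std)
  }
  fit <- tryCatch(
    if (method == "ivw") {
      MASS::rlm(y ~ x - 1, weights = w, wt.method = "inv.var",
                method = "MM", psi = MASS::psi.bisquare, c = 4.685,
                maxit = 200, acc = 1e-8)
    } else {
      MASS::rlm(y ~ x, weights = w, wt.method = "inv.var",
                method = "MM", psi = MASS::psi.bisquare, c = 4.685,
                maxit = 200, acc = 1e-8)
    },
    error = function(e) stop("robust fit failed: ", conditionMessage(e))
  )
  if (!fit$converged) {
    stop("robust MM-estimation did not converge in 200 iterations; ",
         "final coefficients: ",
         paste(signif(stats::coef(fit), 6), collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  if (method == "ivw") {
    mr_result_row("robust_ivw", beta = cf["x", "Value"],
                  se = cf["x", "Std. Error"], n_variants = nrow(variants))
  } else {
    int_se <- cf["(Intercept)", "Std. Error"]
    mr_result_row("robust_egger", beta = cf["x", "Value"],
                  se = cf["x", "Std. Error"], n_variants = nrow(variants),
                  intercept = cf["(Intercept)", "Value"],
                  intercept_se = int_se,
                  intercept_p = 2 * stats::pnorm(
                    -abs(cf["(Intercept)", "Value"] / int_se)))
  }
}

#' Nested-subset sensitivity analysis
#'
#' Refits the IVW estimator on each nested prefix of a stated variant
#' ordering (sizes 2, 3, ..., k). The canonical ordering starts from the
#' two variants in the 25-OHD synthesis pathway genes (CYP2R1, DHCR7) and
#' sequentially adds the remaining variants, so pleiotropy entering with a
#' particular variant shows up as a shift in the estimate sequence.
#'
#' @inheritParams mr_ivw
#' @param order Character vector (length >= 2) of variant ids present in
#'   `variants`, defining the nesting order.
#' @return A `data.frame` with one IVW result row per prefix, plus a
#'   `variants_used` column.
#' @export
mr_subset_sensitivity <- function(variants,
                                  order = c("rs10741657", "rs12785878",
                                            "rs17216707", "rs10745742",
                                            "rs8018720", "rs3755967")) {
  validate_variants(variants)
  unknown <- setdiff(order, variants$variant_id)
  if (length(unknown)) {
    stop("unknown variant id(s) in order: ", paste(unknown, collapse = ", "))
  }
  if (length(order) < 2L) stop("order must list at least two variant ids")
  rows <- lapply(2:length(order), function(k) {
    sub <- variants[match(order[1:k], variants$variant_id), , drop = FALSE]
    res <- mr_ivw(sub)
    res$variants_used <- paste(order[1:k], collapse = ",")
    res
  })
  do.call(rbind, rows)
}

#' Full summary-statistics MR method table
#'
#' Runs the whole battery of summary-statistics estimators on one
#' harmonized variant set and returns the stacked results table (one row
#' per method), mirroring the standard main-results layout: IVW, robust
#' IVW, penalised IVW, MR-Egger, robust MR-Egger, penalised MR-Egger,
#' simple median, weighted median, penalised weighted median.
#'
#' @inheritParams mr_median
#' @param methods Character vector choosing a subset of
#'   `c("ivw", "robust_ivw", "penalized_ivw", "egger", "robust_egger",
#'   "penalized_egger", "simple_median", "weighted_median",
#'   "penalized_weighted_median")`.
#' @return A `data.frame`, one row per method.
#' @export
mr_summary_table <- function(variants,
                             methods = c("ivw", "robust_ivw", "penalized_ivw",
                                         "egger", "robust_egger",
                                         "penalized_egger", "simple_median",
                                         "weighted_median",
                                         "penalized_weighted_median"),
                             n_boot = 10000L, seed = 42L) {
  variants <- harmonize_variants(variants)
  runners <- list(
    ivw = function() mr_ivw(variants),
    robust_ivw = function() mr_robust(variants, "ivw"),
    penalized_ivw = function() mr_penalized(variants, "ivw"),
    egger = function() mr_egger(variants),
    robust_egger = function() mr_robust(variants, "egger"),
    penalized_egger = function() mr_penalized(variants, "egger"),
    simple_median = function() mr_median(variants, "simple", n_boot, seed),
    weighted_median = function() mr_median(variants, "weighted", n_boot, seed),
    penalized_weighted_median = function()
      mr_penalized(variants, "weighted_median", n_boot, seed)
  )
  unknown <- setdiff(methods, names(runners))
  if (length(unknown)) stop("unknown method(s): ", paste(unknown, collapse = ", "))
  out <- do.call(rbind, lapply(runners[methods], function(f) f()))
  rownames(out) <- NULL
  out
}

#' Write an MR results table
#'
#' Tab-separated, full precision (17 significant digits), one row per
#' method; round-trips through [utils::read.delim()] exactly.
#'
#' @param results A results `data.frame` (e.g. from [mr_summary_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
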