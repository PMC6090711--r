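# Individual-level MR: genetic risk score instrument, two-stage
# regressions, Wald coefficient-ratio estimate with Taylor-expansion SE,
# and cross-cohort random-effects meta-analysis.

#' Construct an individual-level MR dataset
#'
#' Bundles an allele-dosage matrix with per-individual phenotypes for one
#' cohort. Dosages count copies of the exposure-increasing allele (values
#' in `[0, 2]`, `NA` allowed); phenotypes carry the exposure
#' (log-transformed 25-OHD, nmol/L; `NA` for individuals without a
#' measurement), binary disease status (`NA` for exposure-only samples),
#' optional covariates `age`, `sex`, `bmi`, and an optional tumour-site
#' label (`proximal`, `distal`, `rectum`) on cases.
#'
#' @param dosages Numeric matrix, individuals x variants, with variant ids
#'   as column names.
#' @param phenotypes `data.frame` with one row per individual; recognised
#'   columns: `exposure`, `outcome`, `age`, `sex`, `bmi`, `site`.
#' @param cohort_id Cohort label.
#' @return An object of class `individual_dataset`.
#' @export
individual_dataset <- function(dosages, phenotypes, cohort_id = "cohort") {
  stopifnot(is.matrix(dosages), is.data.frame(phenotypes))
  if (nrow(dosages) != nrow(phenotypes)) {
    stop("dosages and phenotypes describe different numbers of individuals")
  }
  if (is.null(colnames(dosages))) {
    stop("dosage matrix must have variant ids as column names")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2) stop("dosages must lie in [0, 2]")
  if (!is.null(phenotypes$outcome)) {
    obs <- phenotypes$outcome[!is.na(phenotypes$outcome)]
    if (length(obs) && !all(obs %in% c(0, 1))) {
      stop("outcome must be binary (0/1) where present")
    }
  }
  structure(list(dosages = dosages, phenotypes = phenotypes,
                 cohort_id = cohort_id),
            class = "individual_dataset")
}

#' @export
print.individual_dataset <- function(x, ...) {
  ph <- x$phenotypes
  cat("<individual_dataset> cohort:", x$cohort_id, "\n",
      " individuals:", nrow(x$dosages),
      " variants:", ncol(x$dosages), "\n",
      " exposure measured:", sum(!is.na(ph$exposure)),
      " cases:", sum(ph$outcome == 1, na.rm = TRUE),
      " controls:", sum(ph$outcome == 0, na.rm = TRUE), "\n")
  invisible(x)
}

#' Genetic risk score
#'
#' Per-individual instrument: the weighted sum of exposure-increasing
#' allele dosages (`weighted`), using external per-allele effect sizes from
#' the exposure GWAS, or the plain allele count (`unweighted`). Missing
#' dosages are mean-imputed per variant within the cohort (count reported
#' via a message).
#'
#' @param data An [individual_dataset()].
#' @param weights Named numeric vector of per-allele exposure effects (or a
#'   `data.frame` with `variant_id` and `beta_exposure` columns, e.g. the
#'   harmonized summary statistics); ignored for `mode = "unweighted"` but
#'   still used to select/align variants.
#' @param mode `"weighted"` or `"unweighted"`.
#' @return Numeric score vector, one value per individual.
#' @export
compute_grs <- function(data, weights, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "individual_dataset"))
  if (is.data.frame(weights)) {
    weights <- stats::setNames(weights$beta_exposure, weights$variant_id)
  }
  if (is.null(names(weights)) || any(!is.finite(weights))) {
    stop("weights must be a finite, named vector of per-allele effects")
  }
  missing_cols <- setdiff(names(weights), colnames(data$dosages))
  if (length(missing_cols)) {
    stop("dosage matrix lacks instrument variant(s): ",
         paste(missing_cols, collapse = ", "))
  }
  g <- data$dosages[, names(weights), drop = FALSE]
  n_missing <- sum(is.na(g))
  if (n_missing > 0L) {
    message("mean-imputing ", n_missing, " missing dosage value(s) in ",
            data$cohort_id)
    for (j in seq_len(ncol(g))) {
      nas <- is.na(g[, j])
      if (any(nas)) g[nas, j] <- mean(g[, j], na.rm = TRUE)
    }
  }
  w <- if (mode == "weighted") unname(weights) else rep(1, length(weights))
  as.vector(g %*% w)
}

covariate_matrix <- function(data, adjust, cohort = data$cohort_id) {
  if (is.null(adjust) || !length(adjust)) return(NULL)
  unknown <- setdiff(adjust, names(data$phenotypes))
  if (length(unknown)) {
    stop("cohort ", cohort, " has no covariate column(s): ",
         paste(unknown, collapse = ", "))
  }
  # per-cohort availability: drop covariates that are entirely unmeasured
  avail <- adjust[vapply(adjust, function(v)
    any(!is.na(data$phenotypes[[v]])), logical(1L))]
  dropped <- setdiff(adjust, avail)
  if (length(dropped)) {
    message("cohort ", cohort, ": covariate(s) unavailable, not adjusted: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(avail)) return(NULL)
  as.matrix(data$phenotypes[avail])
}

#' Stage 1: instrument-exposure regression
#'
#' Ordinary least squares of the (log-transformed) exposure on the genetic
#' risk score, optionally adjusted for covariates; individuals missing the
#' exposure or an adjusted covariate are dropped (complete case). Reports
#' the instrument coefficient, its SE, the model R-squared, and the
#' F-statistic for the score term (`t^2`, which for the univariable model
#' equals `(n - 2) R^2 / (1 - R^2)`); F < 10 flags a weak instrument.
#'
#' @param data An [individual_dataset()] with exposure measurements.
#' @param grs Score vector from [compute_grs()].
#' @param adjust Optional character vector of covariate names
#'   (e.g. `c("age", "sex", "bmi")`).
#' @return A list of class `stage1_fit`: `beta1`, `se1`, `f_statistic`,
#'   `r2`, `n`, `weak_instrument`.
#' @export
stage1_exposure_regression <- function(data, grs, adjust = NULL) {
  stopifnot(inherits(data, "individual_dataset"))
  y <- data$phenotypes$exposure
  if (is.null(y) || all(is.na(y))) {
    stop("cohort ", data$cohort_id, " has no exposure measurements")
  }
  if (sum(!is.na(y)) < 30L) {
    stop("need at least 30 individuals with measured exposure")
  }
  X <- cbind(`(Intercept)` = 1, grs = grs, covariate_matrix(data, adjust))
  fit <- ols_fit(y, X)
  f_stat <- (fit$beta[2L] / fit$se[2L])^2
  structure(list(beta1 = fit$beta[2L], se1 = fit$se[2L],
                 f_statistic = f_stat, r2 = fit$r2, n = fit$n,
                 weak_instrument = f_stat < 10,
                 adjust = adjust, cohort_id = data$cohort_id),
            class = "stage1_fit")
}

#' Stage 2: instrument-outcome regression
#'
#' Maximum-likelihood logistic regression of case status on the genetic
#' risk score, optionally adjusted for covariates (complete case within
#' cohort). Errors on apparent separation with the offending coefficients.
#'
#' @inheritParams stage1_exposure_regression
#' @return A list of class `stage2_fit`: `beta2`, `se2`, `n`.
#' @export
stage2_outcome_regression <- function(data, grs, adjust = NULL) {
  stopifnot(inherits(data, "individual_dataset"))
  y <- data$phenotypes$outcome
  if (is.null(y) || !any(y == 1, na.rm = TRUE) || !any(y == 0, na.rm = TRUE)) {
    stop("cohort ", data$cohort_id, " needs both cases and controls")
  }
  X <- cbind(`(Intercept)` = 1, grs = grs, covariate_matrix(data, adjust))
  fit <- logistic_fit(y, X)
  structure(list(beta2 = fit$beta[2L], se2 = fit$se[2L], n = fit$n,
                 adjust = adjust, cohort_id = data$cohort_id),
            class = "stage2_fit")
}

#' Instrument-confounder association scan
#'
#' Tests, among controls only, whether the genetic risk score is associated
#' with each named potential confounder — a violation check for the
#' exchangeability assumption. Continuous confounders are tested by linear
#' regression of the confounder on the score, binary ones by logistic
#' regression, and categorical ones by a global F-test (ANOVA of the score
#' across categories). Associations with p < 0.05 are flagged.
#'
#' @inheritParams stage1_exposure_regression
#' @param confounders Character vector of phenotype column names.
#' @return `data.frame` with columns `confounder`, `type`, `n`, `p_value`,
#'   `flagged` (empty for an empty confounder set).
#' @export
confounder_scan <- function(data, grs, confounders) {
  stopifnot(inherits(data, "individual_dataset"))
  if (!length(confounders)) {
    return(data.frame(confounder = character(), type = character(),
                      n = integer(), p_value = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  unknown <- setdiff(confounders, names(data$phenotypes))
  if (length(unknown)) {
    stop("unknown confounder(s): ", paste(unknown, collapse = ", "))
  }
  ctrl <- which(!is.na(data$phenotypes$outcome) & data$phenotypes$outcome == 0)
  if (!length(ctrl)) stop("no controls available for the confounder scan")
  rows <- lapply(confounders, function(nm) {
    v <- data$phenotypes[[nm]][ctrl]
    s <- grs[ctrl]
    ok <- !is.na(v) & is.finite(s)
    v <- v[ok]; s <- s[ok]
    if (is.numeric(v) && length(unique(v)) > 2L) {
      fit <- uni_linear(v, s)
      p <- 2 * stats::pnorm(-abs(fit$beta / fit$se))
      type <- "continuous"
    } else if (is.numeric(v) || is.logical(v)) {
      fit <- logistic_fit(as.numeric(factor(v)) - 1, cbind(1, s))
      p <- 2 * stats::pnorm(-abs(fit$beta[2L] / fit$se[2L]))
      type <- "binary"
    } else {
      av <- stats::anova(stats::lm(s ~ factor(v)))
      p <- av$`Pr(>F)`[1L]
      type <- "categorical"
    }
    data.frame(confounder = nm, type = type, n = length(v), p_value = p,
               flagged = p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wald coefficient-ratio causal estimate
#'
#' The causal log-odds ratio per unit exposure is the ratio of the stage-2
#' (instrument-outcome) to the stage-1 (instrument-exposure) coefficient,
#' `beta2 / beta1`. Its standard error is the first-order Taylor expansion
#' carrying both sampling variances (the two stages come from independent
#' samples, so no covariance term):
#' \deqn{se = \sqrt{se_2^2/\beta_1^2 + \beta_2^2 se_1^2/\beta_1^4}.}
#'
#' @param stage1 A `stage1_fit` (or any list with `beta1`, `se1`).
#' @param stage2 A `stage2_fit` (or any list with `beta2`, `se2`).
#' @param cohort_id Label for the result row (defaults to the stage-2
#'   cohort).
#' @return One-row `data.frame` of class `two_stage_result`: `cohort_id`,
#'   `beta1`, `se1`, `beta2`, `se2`, `causal_beta`, `causal_se`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `f_statistic`.
#' @export
wald_two_stage <- function(stage1, stage2, cohort_id = NULL) {
  if (stage1$beta1 == 0) stop("stage-1 coefficient is zero; ratio undefined")
  if (!is.null(stage1$adjust) && !is.null(stage2$adjust) &&
      !setequal(stage1$adjust, stage2$adjust)) {
    warning("stage-1 and stage-2 adjustment sets differ (",
            paste(stage1$adjust, collapse = ","), " vs ",
            paste(stage2$adjust, collapse = ","), ")")
  }
  b1 <- stage1$beta1; s1 <- stage1$se1
  b2 <- stage2$beta2; s2 <- stage2$se2
  beta <- b2 / b1
  se <- sqrt(s2^2 / b1^2 + b2^2 * s1^2 / b1^4)
  res <- data.frame(
    cohort_id = if (is.null(cohort_id)) stage2$cohort_id else cohort_id,
    beta1 = b1, se1 = s1, beta2 = b2, se2 = s2,
    causal_beta = beta, causal_se = se,
    or = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    f_statistic = if (!is.null(stage1$f_statistic)) stage1$f_statistic
                  else NA_real_,
    stringsAsFactors = FALSE
  )
  class(res) <- c("two_stage_result", class(res))
  res
}

#' Random-effects meta-analysis of cohort causal estimates
#'
#' DerSimonian-Laird inverse-variance meta-analysis: fixed weights
#' `u_i = 1/se_i^2` give Cochran's `Q = sum u_i (b_i - b_fixed)^2`; the
#' between-cohort variance is the moment estimator
#' `tau2 = max(0, (Q - (m-1)) / (sum u - sum u^2 / sum u))`, and the pooled
#' estimate uses random-effects weights `1/(se_i^2 + tau2)`. Heterogeneity
#' is flagged at `p_het < 0.10`.
#'
#' @param results A `data.frame` of per-cohort estimates with columns
#'   `causal_beta` and `causal_se` (e.g. stacked [wald_two_stage()] rows).
#' @return A list of class `mr_meta`: `pooled_beta`, `pooled_se`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `tau2`, `q_stat`, `p_het`,
#'   `heterogeneity_flag`, `cohort_estimates`.
#' @export
meta_analyze <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("causal_beta", "causal_se") %in% names(results)))
  b <- results$causal_beta
  s <- results$causal_se
  m <- length(b)
  if (m < 1L) stop("no cohort estimates to combine")
  if (m == 1L) {
    message("single cohort estimate: returned unchanged (tau2 = 0)")
    tau2 <- 0; q <- 0; p_het <- NA_real_
    pooled <- b; pooled_se <- s
  } else {
    u <- 1 / s^2
    b_fixed <- sum(u * b) / sum(u)
    q <- sum(u * (b - b_fixed)^2)
    p_het <- stats::pchisq(q, df = m - 1L, lower.tail = FALSE)
    tau2 <- max(0, (q - (m - 1L)) / (sum(u) - sum(u^2) / sum(u)))
    w <- 1 / (s^2 + tau2)
    pooled <- sum(w * b) / sum(w)
    pooled_se <- sqrt(1 / sum(w))
  }
  structure(list(
    pooled_beta = pooled, pooled_se = pooled_se,
    or = exp(pooled), ci_low = exp(pooled - 1.96 * pooled_se),
    ci_high = exp(pooled + 1.96 * pooled_se),
    p_value = 2 * stats::pnorm(-abs(pooled / pooled_se)),
    tau2 = tau2, q_stat = q, p_het = p_het,
    heterogeneity_flag = isTRUE(p_het < 0.10),
    cohort_estimates = results
  ), class = "mr_meta")
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf(
    "<mr_meta> pooled OR %.2f (%.2f-%.2f), P = %.3g  [%d cohort(s)]\n",
    x$or, x$ci_low, x$ci_high, x$p_value, nrow(x$cohort_estimates)))
  cat(sprintf("  tau2 = %.4g, Q = %.3g, P_het = %.3g\n",
              x$tau2, x$q_stat, x$p_het))
  invisible(x)
}

#' Individual-level MR across cohorts
#'
#' The full genetic-risk-score two-stage analysis: the instrument-exposure
#' coefficient is estimated once, in the designated exposure subsample (the
#' only sample with measured 25-OHD, emulating the control series with
#' biomarker data), and reused for every outcome cohort; each cohort
#' contributes an instrument-outcome logistic coefficient, a Wald ratio
#' with Taylor-expansion SE (which propagates the shared stage-1
#' uncertainty), and the cohort estimates are pooled by DerSimonian-Laird
#' random-effects meta-analysis.
#'
#' @param datasets List of [individual_dataset()] outcome cohorts.
#' @param exposure_data [individual_dataset()] providing the exposure
#'   subsample for stage 1.
#' @param weights Per-allele exposure weights (see [compute_grs()]).
#' @param mode `"weighted"` or `"unweighted"` score.
#' @param adjust Covariates for both stages (applied per cohort based on
#'   availability).
#' @param site Optional tumour-site label (`"proximal"`, `"distal"`,
#'   `"rectum"`): restrict stage 2 to cases of that site versus all
#'   controls (site-stratified analysis).
#' @return An `mr_meta` object (see [meta_analyze()]) with the shared
#'   `stage1` fit attached.
#' @export
mr_individual <- function(datasets, exposure_data, weights,
                          mode = c("weighted", "unweighted"),
                          adjust = NULL, site = NULL) {
  mode <- match.arg(mode)
  if (inherits(datasets, "individual_dataset")) datasets <- list(datasets)
  grs_exp <- compute_grs(exposure_data, weights, mode)
  s1 <- stage1_exposure_regression(exposure_data, grs_exp, adjust)
  rows <- lapply(datasets, function(d) {
    if (!is.null(site)) d <- restrict_to_site(d, site)
    g <- compute_grs(d, weights, mode)
    s2 <- stage2_outcome_regression(d, g, adjust)
    wald_two_stage(s1, s2)
  })
  meta <- meta_analyze(do.call(rbind, rows))
  meta$stage1 <- s1
  meta
}

restrict_to_site <- function(data, site) {
  known <- c("proximal", "distal", "rectum")
  if (!site %in% known) {
    stop("unknown tumour site '", site, "' (expected one of: ",
         paste(known, collapse = ", "), ")")
  }
  ph <- data$phenotypes
  is_case <- !is.na(ph$outcome) & ph$outcome == 1
  keep_case <- is_case & !is.na(ph$site) & ph$site == site
  if (!any(keep_case)) {
    stop("cohort ", data$cohort_id, " has no '", site, "' cases")
  }
  keep <- keep_case | (!is.na(ph$outcome) & ph$outcome == 0)
  individual_dataset(data$dosages[keep, , drop = FALSE],
                     ph[keep, , drop = FALSE],
                     paste0(data$cohort_id, ":", site))
}

#' Site-stratified individual-level MR
#'
#' Repeats the two-stage analysis for each tumour-site stratum, using cases
#' of that site against all controls of each cohort (controls are reused
#' across strata).
#'
#' @inheritParams mr_individual
#' @param sites Site labels to analyse.
#' @return Named list of `mr_meta` objects, one per site.
#' @export
mr_stratified <- function(datasets, exposure_data, weights,
                          mode = c("weighted", "unweighted"),
                          adjust = NULL,
                          sites = c("proximal", "distal", "rectum")) {
  mode <- match.arg(mode)
  stats::setNames(lapply(sites, function(s) {
    mr_individual(datasets, exposure_data, weights, mode, adjust, site = s)
  }), sites)
}
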