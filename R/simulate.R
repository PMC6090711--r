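# Synthetic cohort generator.
#
# Emulates the statistical structure the MR analysis assumes: six
# independent biallelic variants in Hardy-Weinberg proportions driving a
# log-normal exposure (instrument R^2 calibrated exactly), a logistic
# case-control outcome with configurable causal effect, per-variant direct
# (pleiotropic) effects, and a shared latent confounder. Covariates are
# generated independently of genotype so the instrument-confounder scan is
# null by construction unless configured otherwise.

default_variant_spec <- function() {
  data.frame(
    variant_id = c("rs10741657", "rs10745742", "rs12785878",
                   "rs17216707", "rs3755967", "rs8018720"),
    effect_allele = c("A", "T", "T", "T", "C", "G"),
    other_allele = c("G", "C", "G", "C", "T", "C"),
    # approximate European-ancestry frequencies of the exposure-increasing
    # alleles; not printed in the source tables, configurable
    freq = c(0.40, 0.40, 0.75, 0.78, 0.72, 0.80),
    # per-allele effects on log 25-OHD, rescaled at simulation time so the
    # six variants jointly explain target_r2 of the exposure variance
    beta_exposure = c(0.0312, 0.0167, 0.0361, 0.0262, 0.0893, 0.0164),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Full generative specification for one synthetic cohort. The per-allele
#' exposure effects in `variant_spec` set the *relative* architecture of
#' the instrument; at simulation time they are rescaled by a single factor
#' so that the genetic variance equals `target_r2 * exposure_sd^2`, and the
#' environmental noise variance is solved analytically as
#' `exposure_sd^2 * (1 - target_r2) - confounder_exposure^2`, so the
#' instrument R-squared and the total exposure SD hold exactly in
#' expectation.
#'
#' The outcome is a logistic model on the linear predictor
#' `intercept + causal_beta * exposure + sum(pleiotropy_k * g_k) +
#' confounder_outcome * U`, with the intercept set so the population risk
#' is about `baseline_risk`. With `case_fraction` set, a case-control
#' sample is drawn by oversampling cases from the simulated population;
#' with `case_fraction = NULL` the cohort is a plain population sample.
#'
#' @param n Number of individuals in the delivered cohort.
#' @param variant_spec `data.frame` with `variant_id`, `freq` (allele
#'   frequency in (0,1)), `beta_exposure`; default: the six-variant 25-OHD
#'   instrument.
#' @param target_r2 Fraction of exposure variance explained by the
#'   instrument (default 0.0284).
#' @param exposure_mean,exposure_sd Mean and SD of the log-transformed
#'   exposure (defaults `log(38)` and 0.5 log-nmol/L).
#' @param causal_beta Causal log-odds ratio of the outcome per unit
#'   log-exposure (default 0).
#' @param pleiotropy Per-variant direct log-odds effects on the outcome
#'   (scalar recycled; default 0).
#' @param confounder_exposure,confounder_outcome Loadings of a latent
#'   standard-normal confounder on exposure (log-nmol/L per SD) and on the
#'   outcome (log-odds per SD); defaults 0.
#' @param baseline_risk Approximate population outcome risk (default 0.01).
#' @param case_fraction Case fraction of the delivered sample (default 0.5)
#'   or `NULL` for a population cohort.
#' @param site_probs Tumour-site distribution among cases.
#' @param site_causal_shift Optional named additive shifts to `causal_beta`
#'   by site type (e.g. `c(distal = -0.5)`).
#' @param measure_exposure Keep the exposure values in the delivered data
#'   (`FALSE` emulates outcome-only cohorts).
#' @param seed RNG seed used by [simulate_cohort()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 5000L,
                       variant_spec = default_variant_spec(),
                       target_r2 = 0.0284,
                       exposure_mean = log(38),
                       exposure_sd = 0.5,
                       causal_beta = 0,
                       pleiotropy = 0,
                       confounder_exposure = 0,
                       confounder_outcome = 0,
                       baseline_risk = 0.01,
                       case_fraction = 0.5,
                       site_probs = c(proximal = 0.35, distal = 0.40,
                                      rectum = 0.25),
                       site_causal_shift = NULL,
                       measure_exposure = TRUE,
                       seed = NULL) {
  stopifnot(is.data.frame(variant_spec),
            all(c("variant_id", "freq", "beta_exposure") %in%
                  names(variant_spec)))
  if (any(variant_spec$freq <= 0 | variant_spec$freq >= 1)) {
    stop("allele frequencies must lie in (0, 1)")
  }
  if (target_r2 <= 0 || target_r2 >= 1) stop("target_r2 must be in (0, 1)")
  r2_max <- 1 - confounder_exposure^2 / exposure_sd^2
  if (exposure_sd^2 * (1 - target_r2) - confounder_exposure^2 <= 0) {
    stop(sprintf(paste0(
      "infeasible target_r2: with confounder_exposure = %g and ",
      "exposure_sd = %g the maximum achievable R2 is %.4g"),
      confounder_exposure, exposure_sd, r2_max))
  }
  k <- nrow(variant_spec)
  pleiotropy <- rep_len(pleiotropy, k)
  if (!is.null(case_fraction) &&
      (case_fraction <= 0 || case_fraction >= 1)) {
    stop("case_fraction must be in (0, 1) or NULL")
  }
  structure(list(
    n = as.integer(n), variant_spec = variant_spec, target_r2 = target_r2,
    exposure_mean = exposure_mean, exposure_sd = exposure_sd,
    causal_beta = causal_beta, pleiotropy = pleiotropy,
    confounder_exposure = confounder_exposure,
    confounder_outcome = confounder_outcome,
    baseline_risk = baseline_risk, case_fraction = case_fraction,
    site_probs = site_probs, site_causal_shift = site_causal_shift,
    measure_exposure = measure_exposure, seed = seed
  ), class = "sim_config")
}

# Rescaled per-allele effects: genetic variance = target_r2 * exposure_sd^2
calibrated_betas <- function(config) {
  vs <- config$variant_spec
  vg_raw <- sum(vs$beta_exposure^2 * 2 * vs$freq * (1 - vs$freq))
  vs$beta_exposure * sqrt(config$target_r2 * config$exposure_sd^2 / vg_raw)
}

draw_population <- function(n, config, betas) {
  vs <- config$variant_spec
  k <- nrow(vs)
  g <- matrix(0L, nrow = n, ncol = k,
              dimnames = list(NULL, vs$variant_id))
  for (j in seq_len(k)) g[, j] <- stats::rbinom(n, 2L, vs$freq[j])
  u <- stats::rnorm(n)
  eps_sd <- sqrt(config$exposure_sd^2 * (1 - config$target_r2) -
                   config$confounder_exposure^2)
  exposure <- config$exposure_mean +
    as.vector(g %*% betas) - sum(betas * 2 * vs$freq) +
    config$confounder_exposure * u + stats::rnorm(n, sd = eps_sd)
  # site labels are only needed up front when they modify the outcome
  # model; otherwise they are sampled for cases after selection
  if (!is.null(config$site_causal_shift)) {
    site_type <- sample(names(config$site_probs), n, replace = TRUE,
                        prob = config$site_probs)
    shift <- config$site_causal_shift[site_type]
    shift[is.na(shift)] <- 0
    causal <- config$causal_beta + unname(shift)
  } else {
    site_type <- NULL
    causal <- config$causal_beta
  }
  # centre the causal term at the exposure mean (per individual, so a
  # site-shifted slope does not shift that stratum's baseline risk)
  intercept <- stats::qlogis(config$baseline_risk) -
    causal * config$exposure_mean -
    sum(config$pleiotropy * 2 * vs$freq)
  lp <- intercept + causal * exposure +
    as.vector(g %*% config$pleiotropy) + config$confounder_outcome * u
  outcome <- stats::rbinom(n, 1L, stats::plogis(lp))
  list(g = g, exposure = exposure, outcome = outcome, site_type = site_type)
}

#' Simulate one synthetic cohort
#'
#' Draws genotypes in Hardy-Weinberg proportions and generates exposure,
#' outcome, covariates and tumour-site labels under the configured model
#' (see [sim_config()]). Case-control designs are sampled by oversampling
#' cases from a population simulation at the configured baseline risk.
#' Deterministic under a fixed `config$seed` (pass `seed` to override).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An [individual_dataset()] with attributes `true_beta` (the
#'   calibrated per-allele exposure effects) and `sim_config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  betas <- calibrated_betas(config)
  n <- config$n
  if (is.null(config$case_fraction)) {
    pop <- draw_population(n, config, betas)
    sel <- seq_len(n)
  } else {
    n_case <- round(n * config$case_fraction)
    n_ctrl <- n - n_case
    g <- NULL; exposure <- NULL; outcome <- NULL; site_type <- NULL
    tries <- 0L
    while (is.null(outcome) || sum(outcome == 1L) < n_case ||
           sum(outcome == 0L) < n_ctrl) {
      tries <- tries + 1L
      if (tries > 25L) stop("case-control sampling failed to accumulate ",
                            "enough cases; raise baseline_risk")
      need_case <- n_case - sum(outcome == 1L)
      chunk <- ceiling(max(need_case / config$baseline_risk * 1.15,
                           n_ctrl * 1.05, 1000))
      add <- draw_population(chunk, config, betas)
      keep <- which(add$outcome == 1L | seq_len(chunk) <= 2L * n)
      g <- rbind(g, add$g[keep, , drop = FALSE])
      exposure <- c(exposure, add$exposure[keep])
      outcome <- c(outcome, add$outcome[keep])
      site_type <- c(site_type, add$site_type[keep])
    }
    sel <- c(which(outcome == 1L)[seq_len(n_case)],
             which(outcome == 0L)[seq_len(n_ctrl)])
    sel <- sel[sample.int(length(sel))]
    pop <- list(g = g[sel, , drop = FALSE], exposure = exposure[sel],
                outcome = outcome[sel],
                site_type = if (is.null(site_type)) NULL
                            else site_type[sel])
    sel <- seq_len(n)
  }
  if (is.null(pop$site_type)) {
    pop$site_type <- sample(names(config$site_probs), n, replace = TRUE,
                            prob = config$site_probs)
  }
  ph <- data.frame(
    exposure = if (config$measure_exposure) pop$exposure else NA_real_,
    outcome = pop$outcome,
    age = stats::rnorm(n, 60, 8),
    sex = stats::rbinom(n, 1L, 0.5),
    bmi = stats::rnorm(n, 27, 4),
    site = ifelse(pop$outcome == 1L, pop$site_type, NA_character_),
    stringsAsFactors = FALSE
  )
  out <- individual_dataset(pop$g, ph, cohort_id = "synthetic")
  attr(out, "true_beta") <- stats::setNames(betas,
                                            config$variant_spec$variant_id)
  attr(out, "sim_config") <- config
  out
}

#' Simulate a two-sample MR design
#'
#' Generates the two non-overlapping samples of a two-sample summary MR:
#' an exposure cohort (population sample with measured exposure, no
#' case-control selection) and an outcome case-control cohort without
#' exposure measurements.
#'
#' @param config A [sim_config()]; `config$n` sets the outcome sample size.
#' @param n_exposure Exposure-cohort size (defaults to `config$n`).
#' @param seed Seed controlling both draws (defaults to `config$seed`).
#' @return List with elements `exposure_cohort`, `outcome_cohort`.
#' @export
simulate_two_sample <- function(config, n_exposure = config$n,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg_exp <- config
  cfg_exp$n <- as.integer(n_exposure)
  cfg_exp$case_fraction <- NULL
  cfg_exp$measure_exposure <- TRUE
  cfg_out <- config
  cfg_out$measure_exposure <- FALSE
  if (is.null(cfg_out$case_fraction)) cfg_out$case_fraction <- 0.5
  exposure_cohort <- simulate_cohort(cfg_exp, seed = NULL)
  exposure_cohort$cohort_id <- "exposure_cohort"
  outcome_cohort <- simulate_cohort(cfg_out, seed = NULL)
  outcome_cohort$cohort_id <- "outcome_cohort"
  list(exposure_cohort = exposure_cohort, outcome_cohort = outcome_cohort)
}

#' Derive two-sample summary statistics from individual-level cohorts
#'
#' Per-variant univariable regressions reproduce the structure of the
#' GWAS inputs to summary-statistics MR: linear regression of the exposure
#' on each dosage in cohort A, logistic regression of the outcome on each
#' dosage in cohort B. Sample overlap between A and B is the caller's
#' concern (identical inputs are accepted with a message).
#'
#' @param cohortA [individual_dataset()] with measured exposure.
#' @param cohortB [individual_dataset()] with case-control outcome.
#' @return A harmonizable summary-statistics `data.frame` (see
#'   [read_summary_stats()] for columns).
#' @export
summarize_to_two_sample <- function(cohortA, cohortB) {
  stopifnot(inherits(cohortA, "individual_dataset"),
            inherits(cohortB, "individual_dataset"))
  ids <- colnames(cohortA$dosages)
  if (!setequal(ids, colnames(cohortB$dosages))) {
    stop("cohorts genotype different variant sets")
  }
  if (identical(cohortA$dosages, cohortB$dosages)) {
    message("cohort A and B carry identical genotypes: one-sample design; ",
            "two-sample standard errors do not account for overlap")
  }
  expo <- cohortA$phenotypes$exposure
  if (all(is.na(expo))) stop("cohort A has no exposure measurements")
  outc <- cohortB$phenotypes$outcome
  if (all(is.na(outc))) stop("cohort B has no outcome data")
  rows <- lapply(ids, function(id) {
    fa <- uni_linear(expo, cohortA$dosages[, id])
    fb <- logistic_fit(outc, cbind(1, cohortB$dosages[, id]))
    data.frame(variant_id = id, gene = NA_character_,
               chromosome = NA_integer_,
               effect_allele = "A1", other_allele = "A2",
               beta_exposure = fa$beta, se_exposure = fa$se,
               beta_outcome = fb$beta[2L], se_outcome = fb$se[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Preset simulation scenarios
#'
#' Fully populated configurations for the study conditions used in
#' validation:
#' \describe{
#'   \item{null}{no causal effect, no pleiotropy, no confounding
#'     (type-I-error checks); n = 5000.}
#'   \item{observational_effect}{causal effect matching an odds ratio of
#'     0.83 per SD of exposure (`causal_beta = log(0.83)/exposure_sd`);
#'     n = 50000.}
#'   \item{pleiotropic}{null causal effect plus directional per-variant
#'     direct effects of +0.05 log-odds per allele, for Egger-intercept
#'     recovery; n = 50000.}
#'   \item{confounded}{null causal effect with a latent confounder loading
#'     0.15 on the exposure and 0.5 on the outcome, demonstrating bias of
#'     naive exposure-outcome regression but not of MR; n = 5000.}
#' }
#'
#' @param name Scenario name.
#' @param n Optional cohort-size override.
#' @param seed Optional seed stored in the config.
#' @return A [sim_config()].
#' @export
sim_scenario <- function(name = c("null", "observational_effect",
                                  "pleiotropic", "confounded"),
                         n = NULL, seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    null = sim_config(n = 5000L, causal_beta = 0, seed = seed),
    observational_effect = sim_config(n = 50000L,
                                      causal_beta = log(0.83) / 0.5,
                                      seed = seed),
    pleiotropic = sim_config(n = 50000L, causal_beta = 0,
                             pleiotropy = 0.05, seed = seed),
    confounded = sim_config(n = 5000L, causal_beta = 0,
                            confounder_exposure = 0.15,
                            confounder_outcome = 0.5, seed = seed)
  )
  if (!is.null(n)) cfg$n <- as.integer(n)
  cfg
}

#' Write a simulated cohort to interchange files
#'
#' Writes the tab-separated dosage matrix (individuals x variants) and
#' phenotype table (`iid exposure outcome age sex bmi site cohort`) that
#' [read_dosage_matrix()] and [read_phenotype_table()] read back.
#'
#' @param data An [individual_dataset()].
#' @param prefix Output path prefix; writes `<prefix>_dosages.tsv` and
#'   `<prefix>_phenotypes.tsv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_cohort <- function(data, prefix) {
  stopifnot(inherits(data, "individual_dataset"))
  dpath <- paste0(prefix, "_dosages.tsv")
  ppath <- paste0(prefix, "_phenotypes.tsv")
  dos <- data.frame(iid = seq_len(nrow(data$dosages)), data$dosages,
                    check.names = FALSE)
  utils::write.table(dos, dpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- data.frame(iid = seq_len(nrow(data$phenotypes)), data$phenotypes,
                   cohort = data$cohort_id, check.names = FALSE)
  utils::write.table(ph, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(dpath, ppath))
}

#' Read a dosage matrix / phenotype table written by [write_cohort()]
#'
#' @param path Tab-separated file path.
#' @return `read_dosage_matrix`: numeric matrix with variant-id columns;
#'   `read_phenotype_table`: `data.frame`.
#' @export
read_dosage_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"iid" %in% names(tab)) stop("dosage file lacks an 'iid' column")
  m <- as.matrix(tab[setdiff(names(tab), "iid")])
  if (!is.numeric(m)) stop("non-numeric dosage values in ", path)
  rownames(m) <- tab$iid
  m
}

#' @rdname read_dosage_matrix
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"iid" %in% names(tab)) stop("phenotype file lacks an 'iid' column")
  tab
}
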