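# End-to-end orchestration used by the analysis drivers: each arm reads
# its inputs, runs the requested estimators, and writes results tables
# plus a structured run log sufficient to reproduce the outputs.

#' Run the summary-statistics MR arm
#'
#' Reads (or accepts) a per-variant summary-statistics table, harmonizes
#' it, runs the requested estimators and the nested-subset sensitivity
#' analysis, and optionally writes the results tables and a run log.
#'
#' @param input Path to a summary-statistics file or a `data.frame`.
#' @param methods Methods passed to [mr_summary_table()].
#' @param n_boot,seed Bootstrap settings for the median methods.
#' @param subset_order Optional variant ordering for
#'   [mr_subset_sensitivity()] (`NULL` skips the sensitivity analysis).
#' @param output_dir Optional directory; when given, writes
#'   `summary_mr_results.tsv`, `subset_sensitivity.tsv` and
#'   `summary_mr_runlog.txt`.
#' @return List with `results`, `subsets`, `variants` (harmonized), `log`.
#' @export
run_summary_mr <- function(input,
                           methods = c("ivw", "robust_ivw", "penalized_ivw",
                                       "egger", "robust_egger",
                                       "penalized_egger", "simple_median",
                                       "weighted_median",
                                       "penalized_weighted_median"),
                           n_boot = 10000L, seed = 42L,
                           subset_order = c("rs10741657", "rs12785878",
                                            "rs17216707", "rs10745742",
                                            "rs8018720", "rs3755967"),
                           output_dir = NULL) {
  variants <- if (is.data.frame(input)) input else read_summary_stats(input)
  variants <- harmonize_variants(variants)
  results <- mr_summary_table(variants, methods = methods,
                              n_boot = n_boot, seed = seed)
  subsets <- if (!is.null(subset_order) &&
                 all(subset_order %in% variants$variant_id)) {
    mr_subset_sensitivity(variants, subset_order)
  } else {
    NULL
  }
  log <- c(
    sprintf("vitdmr %s | R %s", utils::packageVersion("vitdmr"),
            getRversion()),
    sprintf("arm: summary | variants: %d | methods: %s",
            nrow(variants), paste(methods, collapse = ",")),
    sprintf("n_boot: %d | seed: %d", n_boot, seed),
    sprintf("input: %s",
            if (is.data.frame(input)) "<data.frame>" else input),
    sprintf("subset_order: %s",
            if (is.null(subset_order)) "<none>"
            else paste(subset_order, collapse = ","))
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_mr_results(results, file.path(output_dir,
                                        "summary_mr_results.tsv"))
    if (!is.null(subsets)) {
      write_mr_results(subsets, file.path(output_dir,
                                          "subset_sensitivity.tsv"))
    }
    writeLines(log, file.path(output_dir, "summary_mr_runlog.txt"))
  }
  list(results = results, subsets = subsets, variants = variants, log = log)
}

#' Run the individual-level MR arm
#'
#' Computes the genetic risk score in every cohort, fits the shared
#' stage-1 model in the exposure subsample, per-cohort stage-2 logistic
#' models, Wald ratios, and the random-effects pooled estimate; optionally
#' repeats the analysis by tumour site and writes results tables and a run
#' log.
#'
#' @inheritParams mr_individual
#' @param stratify_sites Optional site labels for stratified analysis.
#' @param output_dir Optional output directory (writes
#'   `individual_mr_results.tsv` and `individual_mr_runlog.txt`).
#' @return List with `overall` (`mr_meta`), `stratified` (named list or
#'   `NULL`), `per_cohort` (`data.frame`), `log`.
#' @export
run_individual_mr <- function(datasets, exposure_data, weights,
                              mode = c("weighted", "unweighted"),
                              adjust = c("age", "sex", "bmi"),
                              stratify_sites = NULL, output_dir = NULL) {
  mode <- match.arg(mode)
  overall <- mr_individual(datasets, exposure_data, weights, mode, adjust)
  strat <- if (!is.null(stratify_sites)) {
    mr_stratified(datasets, exposure_data, weights, mode, adjust,
                  sites = stratify_sites)
  } else {
    NULL
  }
  per_cohort <- overall$cohort_estimates
  pooled_row <- data.frame(
    cohort_id = "pooled", beta1 = overall$stage1$beta1,
    se1 = overall$stage1$se1, beta2 = NA_real_, se2 = NA_real_,
    causal_beta = overall$pooled_beta, causal_se = overall$pooled_se,
    or = overall$or, ci_low = overall$ci_low, ci_high = overall$ci_high,
    p_value = overall$p_value, f_statistic = overall$stage1$f_statistic,
    stringsAsFactors = FALSE
  )
  table_out <- rbind(as.data.frame(per_cohort), pooled_row)
  log <- c(
    sprintf("vitdmr %s | R %s", utils::packageVersion("vitdmr"),
            getRversion()),
    sprintf("arm: individual | cohorts: %d | mode: %s | adjust: %s",
            length(datasets), mode, paste(adjust, collapse = ",")),
    sprintf("stage1: beta1=%.6g se1=%.6g F=%.4g n=%d weak=%s",
            overall$stage1$beta1, overall$stage1$se1,
            overall$stage1$f_statistic, overall$stage1$n,
            overall$stage1$weak_instrument),
    sprintf("pooled: OR=%.4g CI=(%.4g, %.4g) p=%.4g tau2=%.4g p_het=%.4g",
            overall$or, overall$ci_low, overall$ci_high, overall$p_value,
            overall$tau2, overall$p_het)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_mr_results(table_out, file.path(output_dir,
                                          "individual_mr_results.tsv"))
    writeLines(log, file.path(output_dir, "individual_mr_runlog.txt"))
  }
  list(overall = overall, stratified = strat, per_cohort = table_out,
       log = log)
}

#' Format a results table the way the main tables print
#'
#' Human-readable rendering: odds ratios to two decimals with the CI as
#' `(low-high)`. The machine-readable table keeps full precision.
#'
#' @param results Results `data.frame` with `method` (or `cohort_id`),
#'   `or`, `ci_low`, `ci_high`, `p_value` columns.
#' @return `data.frame` with `method`, `estimate`, `p_value` (character).
#' @export
format_or_table <- function(results) {
  label <- if ("method" %in% names(results)) results$method
           else results$cohort_id
  data.frame(
    method = label,
    estimate = sprintf("%.2f (%.2f-%.2f)", results$or, results$ci_low,
                       results$ci_high),
    p_value = sprintf("%.3f", results$p_value),
    stringsAsFactors = FALSE
  )
}
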