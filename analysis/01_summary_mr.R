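#!/usr/bin/env Rscript
# Summary-statistics MR of circulating 25-OHD on colorectal cancer risk.
#
# Runs the full estimator battery (IVW, MR-Egger, median-based, penalised
# and robust variants) on the bundled six-variant instrument, plus the
# nested-subset sensitivity analysis, and writes the results tables.
#
# Finding: no method supports a causal effect — IVW OR 0.91 (0.69-1.19)
# per unit log-transformed 25-OHD, Egger intercept compatible with zero
# (no evidence of unbalanced pleiotropy), no heterogeneity (P_het > 0.10),
# and no nested variant subset is significant.

library(vitdmr)

res <- run_summary_mr(vitd_crc_variants(), n_boot = 10000L, seed = 42L,
                      output_dir = "results")

cat("\nMain MR results (per unit log-transformed 25-OHD, nmol/L):\n")
print(format_or_table(res$results), row.names = FALSE)

ivw <- res$results[res$results$method == "ivw", ]
cat(sprintf("\nHeterogeneity across the six variants: Q = %.2f, P = %.3f\n",
            ivw$q_stat, ivw$p_het))
egger <- res$results[res$results$method == "egger", ]
cat(sprintf("Egger intercept: %.4f (SE %.4f), P = %.3f\n",
            egger$intercept, egger$intercept_se, egger$intercept_p))

cat("\nNested-subset sensitivity (IVW on growing variant sets):\n")
print(cbind(format_or_table(res$subsets),
            n_variants = res$subsets$n_variants), row.names = FALSE)
cat("\nTables written under results/.\n")
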