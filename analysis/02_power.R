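#!/usr/bin/env Rscript
# Analytic power of the MR design for a binary outcome.
#
# The six-variant score explains about 2.84% of 25-OHD variance. At the
# observational protective effect (OR 0.83 per SD of 25-OHD) the
# individual-level design (9,940 cases / 22,848 controls) has power ~0.72;
# it reaches 0.80 for effects of a 19% or larger risk decrease per SD. The
# summary-level design (17,716 cases / 40,095 controls) reaches 0.80 at a
# 14.3% decrease but only ~0.49 if the true effect is a 10% decrease.

library(vitdmr)

r2 <- 0.0284

cat("Individual-level design (9,940 / 22,848):\n")
for (or in c(0.83, 0.81)) {
  cat(sprintf("  OR %.2f per SD -> power %.2f\n", or,
              mr_power_binary(9940, 22848, r2, or)))
}
cat("Summary-level design (17,716 / 40,095):\n")
for (or in c(0.857, 0.90)) {
  cat(sprintf("  OR %.3f per SD -> power %.2f\n", or,
              mr_power_binary(17716, 40095, r2, or)))
}

grid <- mr_power_grid(17716, 40095,
                      or_values = seq(0.60, 0.98, by = 0.02),
                      r2_values = c(0.01, 0.02, 0.0284, 0.04, 0.05))
dir.create("results", showWarnings = FALSE)
utils::write.table(grid, "results/power_grid.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nPower grid (OR 0.60-0.98 x instrument R2) written to",
    "results/power_grid.tsv\n")
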