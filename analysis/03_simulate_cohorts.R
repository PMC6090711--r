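#!/usr/bin/env Rscript
# Generate the synthetic individual-level study: an exposure subsample
# with measured log 25-OHD (emulating the 2,821 biomarker controls) and
# five case-control cohorts matching the study's case/control sizes, all
# under the null (no causal effect, no pleiotropy, no confounding).
#
# Raw cohort files are large and go under scratch/ (regenerable); the
# analysis tables built from them are written by 04_individual_mr.R.

library(vitdmr)

sizes <- list(scotland1 = c(932, 942), soccs_gs = c(4551, 8804),
              croatia = c(689, 441), soccs_lbc = c(461, 1444),
              uk_biobank = c(3301, 11382))

set.seed(20260920)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)

exposure_cohort <- simulate_cohort(
  sim_config(n = 2821L, case_fraction = NULL), seed = NULL)
exposure_cohort$cohort_id <- "exposure_subsample"
write_cohort(exposure_cohort, "scratch/sim/exposure_subsample")

for (nm in names(sizes)) {
  sz <- sizes[[nm]]
  d <- simulate_cohort(sim_config(n = sum(sz),
                                  case_fraction = sz[1L] / sum(sz)),
                       seed = NULL)
  d$cohort_id <- nm
  write_cohort(d, file.path("scratch/sim", nm))
  cat(sprintf("  %-12s %5d cases / %5d controls written\n",
              nm, sz[1L], sz[2L]))
}
cat("Synthetic cohorts written under scratch/sim/.\n")
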