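Package: vitdmr
Title: Mendelian Randomisation Analysis of Circulating Vitamin D and
    Colorectal Cancer Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample and individual-level Mendelian randomisation (MR)
    analysis of circulating 25-hydroxyvitamin D (25-OHD) and colorectal
    cancer risk, built around a six-variant genetic instrument. Implements
    the inverse-variance-weighted estimator from per-variant summary
    statistics, MR-Egger regression with its intercept test for unbalanced
    pleiotropy, simple and weighted median estimators with parametric
    bootstrap standard errors, penalised and robust (MM-estimation)
    variants, nested-subset sensitivity analysis, genetic-risk-score
    two-stage estimation on individual-level data with Wald coefficient
    ratios and Taylor-expansion standard errors, DerSimonian-Laird
    random-effects meta-analysis across cohorts, analytic power
    calculation for MR with a binary outcome, and a synthetic cohort
    generator emulating the case-control study design so that every stage
    is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
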