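---
title: "Methods: Mendelian randomisation of circulating vitamin D and colorectal cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomisation of circulating vitamin D and colorectal cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The question and the design

Observational studies consistently find that lower circulating
25-hydroxyvitamin D (25-OHD) accompanies higher colorectal cancer (CRC)
risk, but supplementation trials have not confirmed a benefit. Mendelian
randomisation (MR) asks whether the association is causal by using
genetic variants as instruments: alleles are allocated at random at
conception, so variants that raise 25-OHD are not confounded by lifestyle
and cannot be caused by pre-clinical disease.

`vitdmr` implements both arms of such an analysis around a six-variant
instrument (rs3755967 in *GC*, rs10741657 in *CYP2R1*, rs12785878 near
*DHCR7/NADSYN1*, rs17216707 in *CYP24A1*, rs10745742 in *AMDHD1*,
rs8018720 in *SEC23A*), which together explain about 2.84% of the
variance of log 25-OHD:

* a **summary-statistics (two-sample) arm**, combining per-variant
  effects on log-transformed 25-OHD (nmol/L) with per-variant log-odds
  effects on CRC from independent GWAS meta-analyses; and
* an **individual-level arm**, collapsing the variants into a genetic
  risk score (GRS) and estimating the causal effect by the ratio of
  two regression coefficients.

All causal estimates are odds ratios per unit log-transformed 25-OHD
(nmol/L) unless explicitly stated per SD. The exposure GWAS scale is
reported as-is; no SD standardisation of the exposure betas is attempted,
because the scale of the source exposure GWAS is not further specified.

## Summary-statistics estimators

Write $x_k$, $y_k$ for the effects of variant $k$ on exposure and
outcome and $s_k$ for the standard error of $y_k$, after *harmonization*
(all $x_k > 0$: each variant oriented to its 25-OHD-increasing allele;
variants with $x_k = 0$ have no defined orientation and are dropped with
a warning).

* **IVW.** $\hat\beta = \sum x_k y_k s_k^{-2} / \sum x_k^2 s_k^{-2}$ with
  $se = (\sum x_k^2 s_k^{-2})^{-1/2}$ — algebraically a weighted
  least-squares fit of $y_k$ on $x_k$ through the origin with the
  residual dispersion fixed at 1 (the package tests verify this
  equivalence to 1e-10 against a generic WLS fit). Heterogeneity is
  Cochran's $Q$ over the per-variant Wald ratios, flagged at $p < 0.10$.
* **Per-variant Wald ratios.** $y_k/x_k$ with first-order SE
  $s_k/|x_k|$. Exposure-side uncertainty is deliberately ignored here,
  for consistency with the IVW standard error above, which involves only
  $s_k$; with instrument F-statistics in the hundreds on the exposure
  GWAS side this second-order term is negligible.
* **MR-Egger.** The same regression with a free intercept. The intercept
  estimates the average directional pleiotropic effect; $p < 0.05$ on
  the intercept flags unbalanced pleiotropy. The residual scale is a
  multiplicative overdispersion parameter floored at one,
  $\max(1, Q_E/(k-2))$ — the convention of the standard two-sample MR
  software, adopted so that under-dispersed small instruments are not
  given anti-conservative confidence intervals. Plain dispersion-1
  errors are available via `overdispersion = FALSE`.
* **Median estimators.** The simple (equal-weight) and weighted
  (inverse-variance weight $x_k^2/s_k^2$) 50th percentile of the sorted
  ratios, interpolated on cumulative weights: ratio $j$ sits at
  percentile $\mathrm{cum}_j - w_j/2$ and the estimate interpolates at
  0.5. The SE is a parametric bootstrap (default 10,000 resamples of
  each ratio from $N(\hat r_k, se_k)$); draws are generated in
  variant-id order so results cannot depend on row order, and the seed
  is a required argument.
* **Penalization.** Each variant's weight is multiplied by
  $\min(1, 20 p_k)$ where $p_k$ is the upper $\chi^2_1$ tail of its
  heterogeneity contribution at the unpenalized estimate. Variants
  consistent with the fit ($p_k \ge 0.05$) keep full weight, so the
  constant 20 only matters for outliers; the bundled instrument has
  none, and its penalised estimates equal the unpenalised ones.
* **Robust regression.** MM-estimation with Tukey's biweight
  (95%-efficiency tuning constant 4.685, tolerance 1e-8, max 200
  iterations) for both the IVW and Egger specifications, via
  `MASS::rlm`. The exact robust settings behind published robust MR fits
  are rarely stated, so comparisons against published robust rows should
  allow about ±0.02 on the OR scale. On an exactly collinear instrument
  the MM scale estimate degenerates, and the robust fit is returned as
  the (identical) standard fit.
* **Nested subsets.** IVW refitted on growing prefixes of a stated
  variant order, by default starting from the 25-OHD-synthesis variants
  (rs10741657, rs12785878) and adding rs17216707, rs10745742, rs8018720,
  rs3755967 — the order in which pleiotropy concerns grow, since the
  later variants sit in genes with broader function.

Significance conventions: causal estimates two-sided at $\alpha = 0.05$;
heterogeneity at $p < 0.10$; all CIs use the normal multiplier 1.96.

## Individual-level arm

The GRS is $\sum_k w_k g_{ik}$ with external weights $w_k$ (the exposure
GWAS betas) or $w_k = 1$ (unweighted). Stage 1 regresses measured log
25-OHD on the score in the designated exposure subsample — in this
design only one sample has the biomarker, so $\beta_1$ is estimated once
and reused by every outcome cohort, with its uncertainty propagated into
each cohort's SE. The instrument F-statistic is the squared $t$ of the
score term, $(n-2)R^2/(1-R^2)$ in the univariable model; $F < 10$ flags
a weak instrument. Stage 2 is a logistic regression of case status on
the score per cohort, adjusted for age, sex and BMI where a cohort has
them (complete-case within cohort, logged). The causal estimate is the
Wald coefficient ratio $\beta_2/\beta_1$ with first-order Taylor SE
$\sqrt{se_2^2/\beta_1^2 + \beta_2^2 se_1^2/\beta_1^4}$; the covariance
term is zero because the two stages use independent samples. When the
two stages are fitted with different adjustment sets the package warns
rather than errors, since availability differs by cohort.

Cohort estimates are pooled by DerSimonian–Laird random-effects
meta-analysis (the moment estimator of $\tau^2$, truncated at zero),
implemented from its closed form and cross-checked in the tests against
`metafor`. Site-stratified analyses (proximal, distal, rectum) reuse all
controls of each cohort against the site's cases.

The instrument-confounder scan regresses each candidate confounder on
the GRS among controls (linear for continuous, logistic for binary, a
global ANOVA F-test for categorical), flagging $p < 0.05$.

## Analytic power

For a binary outcome the package uses the normal-approximation method of
the standard MR power calculator for case-control designs: with total
$N$, case fraction $K$, instrument $R^2$ and hypothesized OR per SD of
exposure, the causal effect is mapped to the risk-difference scale,
$b = K\,(\mathrm{OR}/(1 + K(\mathrm{OR}-1)) - 1)$,
$v = K(1-K) - b^2$, and power is the upper tail of a non-central
$\chi^2_1$ with NCP $= N R^2 b^2 / v$ at the $1-\alpha$ quantile. The
published design values pin this transcription: power 0.72 at OR 0.83
per SD with 9,940/22,848 cases/controls, 0.80 by OR $\approx$ 0.81;
0.80 at OR 0.857 and 0.49 at OR 0.90 with 17,716/40,095.

One caveat discovered while testing: this formula is *not* exactly
symmetric in $\mathrm{OR} \leftrightarrow 1/\mathrm{OR}$ (the
attenuation term $b$ is asymmetric; at $K = 0.3$ the difference reaches
several power points for ORs far from 1). The method's true symmetry is
the case/control label swap $(K, \mathrm{OR}) \to (1-K, 1/\mathrm{OR})$,
which the tests assert instead. The tests also check the formula against
an empirical rejection rate of the full simulated two-stage pipeline.

## The synthetic-data generator

No individual-level cohort data can ship with the package, so every
individual-level path is exercised on synthetic cohorts with the
structure the analysis assumes:

* genotypes in Hardy–Weinberg proportions at six independent variants.
  Allele frequencies default to approximate European-ancestry values for
  the six instrument variants (0.40, 0.40, 0.75, 0.78, 0.72, 0.80);
  they are **not** derived from the source tables, which do not print
  frequencies, and are configurable;
* exposure $= \mu + \sum \beta_k g_k + \gamma U + \varepsilon$ on the
  log-nmol/L scale. Defaults $\mu = \log 38$, total SD 0.5, chosen so
  that one exposure SD is a meaningful contrast for a low-latitude
  deficient population; these are modelling choices, not published
  values. The relative sizes of the $\beta_k$ follow the instrument's
  exposure betas, rescaled by one common factor so the instrument
  explains exactly `target_r2` (default 2.84%) of the exposure variance;
  the noise SD is then solved analytically, and infeasible requests
  (confounder variance exceeding the non-genetic budget) error with the
  analytic maximum;
* outcome from a logistic model with linear predictor
  $a + \beta_c \cdot \mathrm{exposure} + \sum \alpha_k g_k + \delta U$,
  intercept set for ~1% population risk; case-control sets are drawn by
  oversampling cases from the simulated population, which preserves
  odds-ratio parameters. Covariates (age, sex, BMI) are generated
  independently of genotype, so the confounder scan is null by
  construction;
* preset scenarios: `null`; `observational_effect`
  ($\beta_c = \log(0.83)/0.5$ per unit log-exposure, i.e. OR 0.83 per
  exposure SD — the observational association the power analysis
  assumes); `pleiotropic` (direct effects $\alpha_k = 0.05$ log-odds per
  allele on all six variants — about three times the largest per-variant
  outcome association, chosen by analytic power so the Egger intercept
  detects it reliably at the scenario's n = 50,000); `confounded`
  ($\gamma = 0.15$, $\delta = 0.5$: enough to visibly bias naive
  exposure-outcome regression while leaving MR valid).

What the generator does **not** emulate: linkage disequilibrium between
variants, population stratification, age-dependent incidence,
measurement error in 25-OHD, seasonality, and sample overlap between the
exposure and outcome samples. Passing simulations therefore validate the
estimators' arithmetic and sampling behaviour under the design's own
assumptions — they do not certify robustness to those real-data
complications, which is exactly why the sensitivity estimators (Egger,
median, penalised, robust) exist in the battery.

## Problem sizes used in validation

The validation suite runs: the deterministic six-variant desk
reproductions; IVW/WLS equivalence on 100 random instruments; type-I
error under the null scenario with 1,000 seeds at n = 5,000 per sample
(accepting rates in the 95% binomial band around 0.05); effect recovery
under `observational_effect` with 200 replicates at n = 50,000 per
sample (mean within 3 Monte-Carlo SEs of the generating value — the
residual non-collapsibility attenuation of logistic marginal effects is
an order of magnitude below that band at this effect size); Egger
intercept detection over 40 pleiotropic replicates; DerSimonian–Laird
$\tau^2$ recovery over 2,000 two-cohort meta-level replicates (with
$\tau^2 = 0.09$ large relative to the within-cohort variance so the
zero-truncation of the estimator rarely binds); and pooled-CI coverage
in 150 replicates of a five-cohort null emulation at the study's
case/control sizes, judged against the 99% binomial band around nominal
95% coverage.

## Worked example

```{r example}
variants <- vitd_crc_variants()
tab <- mr_summary_table(variants, n_boot = 10000, seed = 42)
format_or_table(tab)

mr_power_binary(9940, 22848, r2 = 0.0284, or_per_sd = 0.83)
```

## Known limitations

* Independence of variants is assumed, not checked: the package has no
  LD machinery, matching the design in which LD pruning happened
  upstream.
* No mode-based, multivariable or non-linear MR estimators.
* The robust-fit tuning reproduces published robust rows only to ~0.02
  on the OR scale, because published analyses rarely pin their robust
  settings.
* Median CIs rely on a normal approximation with a bootstrap SE; for
  very few variants (3-4) the bootstrap distribution can be visibly
  non-normal.
* The shared stage-1 coefficient makes cohort estimates weakly
  correlated through $\beta_1$; the meta-analysis treats them as
  independent. Under the null this is immaterial (the shared term is
  proportional to $\beta_2 \approx 0$), and the coverage simulation
  confirms near-nominal behaviour.
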