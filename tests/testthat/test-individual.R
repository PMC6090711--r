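make_dataset <- function(n = 400L, seed = 1L, with_outcome = TRUE) {
  set.seed(seed)
  g <- sapply(c(0.4, 0.4, 0.75, 0.78, 0.72, 0.8),
              function(f) rbinom(n, 2L, f))
  colnames(g) <- six_variants()$variant_id
  ph <- data.frame(
    exposure = rnorm(n, log(38), 0.5),
    outcome = if (with_outcome) rbinom(n, 1L, 0.5) else NA_integer_,
    age = rnorm(n, 60, 8), sex = rbinom(n, 1L, 0.5), bmi = rnorm(n, 27, 4),
    site = NA_character_, stringsAsFactors = FALSE
  )
  individual_dataset(g, ph, "toy")
}

test_that("the genetic risk score sums weighted exposure-allele dosages", {
  d <- make_dataset(n = 5L)
  d$dosages[,] <- 2
  w <- setNames(six_variants()$beta_exposure, six_variants()$variant_id)
  expect_equal(compute_grs(d, w, "weighted"), rep(0.4318, 5L))
  expect_equal(compute_grs(d, w, "unweighted"), rep(12, 5L))
  # unit weights reproduce the unweighted score bit for bit
  unit <- setNames(rep(1, 6L), names(w))
  expect_identical(compute_grs(d, unit, "weighted"),
                   compute_grs(d, w, "unweighted"))
})

test_that("GRS construction validates alignment and imputes missingness", {
  d <- make_dataset()
  w <- setNames(rep(0.03, 7L), c(colnames(d$dosages), "rs_absent"))
  expect_error(compute_grs(d, w, "weighted"), "rs_absent")
  d2 <- make_dataset()
  d2$dosages[1:5, 2L] <- NA
  w6 <- setNames(six_variants()$beta_exposure, colnames(d2$dosages))
  expect_message(g <- compute_grs(d2, w6, "weighted"), "mean-imputing")
  expect_true(all(is.finite(g)))
})

test_that("stage-1 F-statistic matches its analytic form", {
  set.seed(7)
  d <- make_dataset(n = 2821L, seed = 7L)
  w <- setNames(six_variants()$beta_exposure, colnames(d$dosages))
  grs <- compute_grs(d, w, "weighted")
  # plant a known instrument-exposure relationship
  d$phenotypes$exposure <- 3 + 1.0 * grs + rnorm(2821L, 0, 0.5)
  s1 <- stage1_exposure_regression(d, grs)
  n <- s1$n
  expect_equal(s1$f_statistic, (n - 2) * s1$r2 / (1 - s1$r2),
               tolerance = 1e-8)
  expect_false(s1$weak_instrument)
  # a perfectly collinear exposure is a degenerate fit
  d$phenotypes$exposure <- 1 + 2 * grs
  expect_error(stage1_exposure_regression(d, grs), "degenerate")
})

test_that("a null instrument is flagged weak at roughly the F < 10 rate", {
  # under independence F ~ F(1, n-2); P(F < 10) is the non-rejection mass
  set.seed(11)
  n_rep <- 300L
  n <- 150L
  flags <- vapply(seq_len(n_rep), function(i) {
    g <- matrix(rbinom(n, 2L, 0.5), ncol = 1L,
                dimnames = list(NULL, "rs1"))
    ph <- data.frame(exposure = rnorm(n), outcome = NA_integer_)
    d <- individual_dataset(g, ph)
    stage1_exposure_regression(d, g[, 1L])$weak_instrument
  }, logical(1L))
  expected <- pf(10, 1, n - 2)
  mc <- sqrt(expected * (1 - expected) / n_rep)
  expect_lt(abs(mean(flags) - expected), 4 * mc)
})

test_that("stage-2 recovers a planted instrument-outcome log-odds slope", {
  set.seed(21)
  n <- 20000L
  g <- matrix(rbinom(n, 2L, 0.5), ncol = 1L, dimnames = list(NULL, "rs1"))
  lp <- -2 + 0.5 * g[, 1L]
  ph <- data.frame(exposure = NA_real_, outcome = rbinom(n, 1L, plogis(lp)))
  d <- individual_dataset(g, ph)
  s2 <- stage2_outcome_regression(d, g[, 1L])
  expect_lt(abs(s2$beta2 - 0.5), 3 * s2$se2)
  # doubling the score halves the coefficient (reparameterization)
  s2b <- stage2_outcome_regression(d, 2 * g[, 1L])
  expect_equal(s2b$beta2, s2$beta2 / 2, tolerance = 1e-6)
})

test_that("Wald two-stage ratio and Taylor SE behave at the edges", {
  s1 <- list(beta1 = 0.055, se1 = 0.008)
  s2 <- list(beta2 = 0, se2 = 0.02)
  res <- wald_two_stage(s1, s2, cohort_id = "x")
  expect_equal(res$causal_beta, 0)
  expect_equal(res$or, 1)
  expect_equal(res$causal_se, 0.02 / 0.055)
  # se1 = 0 reduces to se2/|beta1|
  res2 <- wald_two_stage(list(beta1 = -0.05, se1 = 0),
                         list(beta2 = 0.01, se2 = 0.02), "x")
  expect_equal(res2$causal_se, 0.02 / 0.05)
  expect_error(wald_two_stage(list(beta1 = 0, se1 = 1),
                              list(beta2 = 1, se2 = 1), "x"), "zero")
})

test_that("the Taylor SE matches a parametric bootstrap of the ratio", {
  s1 <- list(beta1 = 0.06, se1 = 0.008)
  s2 <- list(beta2 = 0.04, se2 = 0.02)
  res <- wald_two_stage(s1, s2, "x")
  set.seed(5150)
  b1 <- rnorm(1e5, s1$beta1, s1$se1)
  b2 <- rnorm(1e5, s2$beta2, s2$se2)
  expect_equal(res$causal_se, sd(b2 / b1), tolerance = 0.05)
})

test_that("the causal estimate is invariant to rescaling the score weights", {
  d_exp <- make_dataset(n = 600L, seed = 31L)
  d_out <- make_dataset(n = 600L, seed = 32L)
  w <- setNames(six_variants()$beta_exposure, colnames(d_exp$dosages))
  base <- suppressMessages(mr_individual(list(d_out), d_exp, w))
  for (c_mult in c(0.1, 3, 100)) {
    scaled <- suppressMessages(mr_individual(list(d_out), d_exp, w * c_mult))
    expect_equal(scaled$pooled_beta, base$pooled_beta, tolerance = 1e-10)
    expect_equal(scaled$pooled_se, base$pooled_se, tolerance = 1e-10)
  }
})

test_that("the confounder scan flags only real instrument-confounder links", {
  d <- make_dataset(n = 2000L, seed = 41L)
  w <- setNames(six_variants()$beta_exposure, colnames(d$dosages))
  grs <- compute_grs(d, w, "weighted")
  # deterministic function of the score: certain detection
  d$phenotypes$bmi <- 20 + 100 * grs
  scan <- confounder_scan(d, grs, c("age", "sex", "bmi"))
  expect_equal(nrow(scan), 3L)
  expect_true(scan$flagged[scan$confounder == "bmi"])
  expect_lt(scan$p_value[scan$confounder == "bmi"], 1e-10)
  expect_equal(nrow(confounder_scan(d, grs, character())), 0L)
  expect_error(confounder_scan(d, grs, "smoking"), "smoking")
})

test_that("scan type-I error for a genotype-independent confounder is nominal", {
  set.seed(51)
  n_rep <- 200L
  flagged <- vapply(seq_len(n_rep), function(i) {
    d <- simulate_cohort(sim_config(n = 400L), seed = NULL)
    w <- attr(d, "true_beta")
    grs <- compute_grs(d, w, "weighted")
    confounder_scan(d, grs, "bmi")$flagged
  }, logical(1L))
  rate <- mean(flagged)
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / n_rep) - 1e-9)
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("categorical confounders get a global association test", {
  d <- make_dataset(n = 1000L, seed = 61L)
  w <- setNames(six_variants()$beta_exposure, colnames(d$dosages))
  grs <- compute_grs(d, w, "weighted")
  d$phenotypes$centre <- sample(c("a", "b", "c"), 1000L, replace = TRUE)
  scan <- confounder_scan(d, grs, "centre")
  expect_equal(scan$type, "categorical")
  expect_true(scan$p_value > 0 && scan$p_value <= 1)
})
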