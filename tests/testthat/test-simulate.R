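test_that("cohort generation is deterministic under a fixed seed", {
  a <- simulate_cohort(sim_scenario("null", seed = 123L))
  b <- simulate_cohort(sim_scenario("null", seed = 123L))
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_cohort(sim_scenario("null", seed = 124L))
  expect_false(identical(a$dosages, c$dosages))
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  d <- simulate_cohort(sim_config(n = 50000L, case_fraction = NULL,
                                  seed = 31L))
  freqs <- sim_config()$variant_spec$freq
  for (j in seq_len(ncol(d$dosages))) {
    f <- freqs[j]
    observed <- tabulate(d$dosages[, j] + 1L, nbins = 3L)
    expected <- 50000 * c((1 - f)^2, 2 * f * (1 - f), f^2)
    p <- chisq.test(observed, p = expected / sum(expected))$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("the instrument explains the configured share of exposure variance", {
  d <- simulate_cohort(sim_config(n = 200000L, case_fraction = NULL,
                                  seed = 32L))
  b <- attr(d, "true_beta")
  vg <- var(as.vector(d$dosages %*% b))
  expect_equal(vg / var(d$phenotypes$exposure), 0.0284, tolerance = 0.002)
  expect_equal(sd(d$phenotypes$exposure), 0.5, tolerance = 0.01)
})

test_that("an unachievable instrument R2 errors with the analytic maximum", {
  expect_error(sim_config(target_r2 = 0.9, confounder_exposure = 0.3),
               "maximum achievable")
  expect_error(sim_config(target_r2 = 1.2), "target_r2")
  expect_error(sim_config(variant_spec = data.frame(
    variant_id = "rs1", freq = 1.2, beta_exposure = 0.05)), "frequencies")
})

test_that("scenario presets encode the intended study conditions", {
  expect_equal(sim_scenario("null")$causal_beta, 0)
  expect_equal(sim_scenario("observational_effect")$causal_beta,
               log(0.83) / 0.5)
  expect_true(all(sim_scenario("pleiotropic")$pleiotropy > 0))
  cfg <- sim_scenario("confounded")
  expect_true(cfg$confounder_exposure > 0 && cfg$confounder_outcome > 0)
  expect_equal(cfg$causal_beta, 0)
  expect_error(sim_scenario("tidal"), "arg")
})

test_that("derived summary statistics recover the generating effects", {
  ts <- simulate_two_sample(sim_scenario("null", n = 20000L, seed = 33L))
  ss <- summarize_to_two_sample(ts$exposure_cohort, ts$outcome_cohort)
  truth <- attr(ts$exposure_cohort, "true_beta")
  expect_equal(ss$variant_id, names(truth))
  # exposure-arm regressions sit within 3 SE of the generating betas
  expect_true(all(abs(ss$beta_exposure - truth) < 3 * ss$se_exposure))
  # null outcome arm: no variant-outcome association beyond noise
  expect_true(all(abs(ss$beta_outcome) < 4 * ss$se_outcome))
  expect_true(all(ss$se_exposure > 0 & ss$se_outcome > 0))
})

test_that("overlapping cohorts are accepted but noted", {
  d <- simulate_cohort(sim_config(n = 2000L, seed = 34L))
  expect_message(ss <- summarize_to_two_sample(d, d), "identical")
  expect_equal(nrow(ss), 6L)
  d2 <- simulate_cohort(sim_config(n = 500L, seed = 35L))
  d3 <- d2
  colnames(d3$dosages)[1L] <- "rs_other"
  expect_error(summarize_to_two_sample(d2, d3), "different variant sets")
})

test_that("a latent confounder biases naive regression but not MR", {
  set.seed(36)
  n_rep <- 30L
  naive_reject <- logical(n_rep)
  ivw_reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- sim_scenario("confounded")
    ts <- simulate_two_sample(cfg, seed = NULL)
    # naive association: outcome on (unobservedly confounded) exposure;
    # the outcome cohort's true exposure is used deliberately
    oc2 <- simulate_cohort(cfg, seed = NULL)
    fit <- suppressWarnings(glm(oc2$phenotypes$outcome ~
                                  oc2$phenotypes$exposure,
                                family = binomial()))
    naive_reject[i] <- summary(fit)$coefficients[2L, 4L] < 0.05
    ss <- summarize_to_two_sample(ts$exposure_cohort, ts$outcome_cohort)
    ivw_reject[i] <- mr_ivw(harmonize_variants(ss))$p_value < 0.05
  }
  expect_gt(mean(naive_reject), 0.9)   # confounding bias is detected
  expect_lt(mean(ivw_reject), 0.30)    # MR stays near its nominal size
})
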