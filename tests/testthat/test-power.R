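test_that("analytic power reproduces the study's published values", {
  # individual-level design at the observed protective effect
  expect_equal(mr_power_binary(9940, 22848, 0.0284, 0.83), 0.72,
               tolerance = 0.02)
  # >= 80% power for a 19% or larger risk decrease per SD
  expect_gte(mr_power_binary(9940, 22848, 0.0284, 0.81), 0.80 - 0.02)
  # summary-level design reaches 0.80 at a 14.3% decrease ...
  expect_equal(mr_power_binary(17716, 40095, 0.0284, 0.857), 0.80,
               tolerance = 0.02)
  # ... and only 0.49 at a 10% decrease
  expect_equal(mr_power_binary(17716, 40095, 0.0284, 0.90), 0.49,
               tolerance = 0.02)
})

test_that("a null effect yields power equal to the test size", {
  expect_equal(mr_power_binary(5000, 5000, 0.0284, 1.0), 0.05,
               tolerance = 1e-10)
  expect_equal(mr_power_binary(5000, 5000, 0.0284, 1.0, alpha = 0.01),
               0.01, tolerance = 1e-10)
})

test_that("power is invariant under swapping the case/control labels", {
  for (or in c(0.6, 0.83, 1.3)) {
    expect_equal(mr_power_binary(9940, 22848, 0.0284, or),
                 mr_power_binary(22848, 9940, 0.0284, 1 / or),
                 tolerance = 1e-12)
  }
})

test_that("power is monotone in sample size, R2 and effect distance", {
  p_small <- mr_power_binary(1000, 2000, 0.0284, 0.83)
  p_big <- mr_power_binary(10000, 20000, 0.0284, 0.83)
  expect_gt(p_big, p_small)
  expect_gt(mr_power_binary(5000, 5000, 0.05, 0.83),
            mr_power_binary(5000, 5000, 0.02, 0.83))
  expect_gt(mr_power_binary(5000, 5000, 0.0284, 0.81),
            mr_power_binary(5000, 5000, 0.0284, 0.83))
  # power approaches 1 for any non-null effect as n grows
  expect_gt(mr_power_binary(5e6, 5e6, 0.0284, 0.98), 0.999)
})

test_that("invalid power parameters are rejected", {
  expect_error(mr_power_binary(0, 100, 0.0284, 0.8), "n_cases")
  expect_error(mr_power_binary(100, 100, 1.2, 0.8), "r2")
  expect_error(mr_power_binary(100, 100, 0.03, -0.5), "or_per_sd")
  expect_error(mr_power_binary(100, 100, 0.03, 0.8, alpha = 1.5), "alpha")
})

test_that("the power grid is consistent with its pointwise evaluations", {
  grid <- mr_power_grid(9940, 22848, or_values = seq(0.6, 0.98, by = 0.02),
                        r2_values = c(0.02, 0.0284, 0.05))
  cell <- grid[grid$or_per_sd == 0.82 & grid$r2 == 0.0284, ]
  expect_equal(cell$power, mr_power_binary(9940, 22848, 0.0284, 0.82))
  # non-decreasing in r2 at fixed OR
  for (or in c(0.6, 0.8, 0.98)) {
    col <- grid[grid$or_per_sd == or, ]
    col <- col[order(col$r2), ]
    expect_true(all(diff(col$power) >= 0))
  }
  # farther from the null at fixed r2 means more power
  col <- grid[grid$r2 == 0.0284, ]
  col <- col[order(col$or_per_sd), ]
  expect_true(all(diff(col$power) <= 0))
  expect_error(mr_power_grid(100, 100, numeric(), 0.03), "non-empty")
})

test_that("analytic power agrees with a simulated two-stage design", {
  # balanced-outcome cohorts; hypothesized OR 0.7 per SD of exposure
  analytic <- mr_power_binary(2000, 2000, 0.0284, 0.7)
  cfg <- sim_config(n = 4000L, causal_beta = log(0.7) / 0.5,
                    baseline_risk = 0.5, case_fraction = NULL)
  cfg_exp <- sim_config(n = 4000L, case_fraction = NULL)
  set.seed(7117)
  n_rep <- 300L
  reject <- vapply(seq_len(n_rep), function(i) {
    d_exp <- simulate_cohort(cfg_exp, seed = NULL)
    d_out <- simulate_cohort(cfg, seed = NULL)
    w <- attr(d_exp, "true_beta")
    res <- suppressMessages(mr_individual(list(d_out), d_exp, w))
    res$p_value < 0.05
  }, logical(1L))
  band <- 1.96 * sqrt(analytic * (1 - analytic) / n_rep)
  # allow for the analytic approximation itself on top of Monte-Carlo noise
  expect_lt(abs(mean(reject) - analytic), band + 0.03)
})
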