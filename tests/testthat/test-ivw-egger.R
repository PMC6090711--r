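test_that("IVW on the six-variant instrument matches the published estimate", {
  res <- mr_ivw(six_variants())
  expect_equal(round(res$or, 2), 0.91)
  expect_equal(round(res$ci_low, 2), 0.69)
  expect_equal(round(res$ci_high, 2), 1.19)
  expect_gt(res$p_value, 0.05)             # no significant causal effect
  expect_equal(res$p_het, 0.547, tolerance = 0.005)
  expect_false(res$p_het < 0.10)           # no significant heterogeneity
})

test_that("single-variant IVW collapses to the Wald ratio exactly", {
  v <- six_variants()[3L, ]
  res <- mr_ivw(v)
  rt <- wald_ratios(v)
  expect_identical(res$beta, rt$ratio)
  expect_identical(res$se, rt$ratio_se)
  expect_error(mr_ivw(six_variants()[0L, ]), "at least one")
})

test_that("homogeneous ratios give beta = r and zero heterogeneity", {
  r <- -0.3
  bx <- c(0.02, 0.04, 0.05, 0.07, 0.03, 0.06)
  v <- make_variants(bx = bx, by = r * bx, sy = runif(6, 0.01, 0.02))
  res <- mr_ivw(v)
  expect_equal(res$beta, r, tolerance = 1e-12)
  expect_equal(res$q_stat, 0, tolerance = 1e-20)
})

test_that("IVW estimators are invariant to row order and allele flips", {
  set.seed(404)
  for (i in 1:20) {
    v <- random_variants(k = sample(3:10, 1L))
    res <- mr_ivw(harmonize_variants(v))
    perm <- v[sample.int(nrow(v)), ]
    rownames(perm) <- NULL
    expect_identical(mr_ivw(harmonize_variants(perm))$beta, res$beta)
    flipped <- v
    j <- sample.int(nrow(v), 1L)
    flipped$beta_exposure[j] <- -flipped$beta_exposure[j]
    flipped$beta_outcome[j] <- -flipped$beta_outcome[j]
    expect_identical(mr_ivw(harmonize_variants(flipped))$beta, res$beta)
    expect_identical(mr_ivw(harmonize_variants(flipped))$se, res$se)
  }
})

test_that("Cochran's Q is minimized at the IVW estimate", {
  set.seed(77)
  for (i in 1:10) {
    v <- harmonize_variants(random_variants())
    res <- mr_ivw(v)
    rt <- wald_ratios(v)
    q_at <- function(b) sum(rt$iv_weight * (rt$ratio - b)^2)
    for (d in c(-0.05, -0.01, 0.01, 0.05)) {
      expect_gt(q_at(res$beta + d), res$q_stat)
    }
  }
})

test_that("MR-Egger on the instrument matches the published slope and CI", {
  res <- mr_egger(six_variants())
  expect_equal(round(res$or, 2), 0.83)
  expect_equal(round(res$ci_low, 2), 0.51)
  expect_equal(round(res$ci_high, 2), 1.34, tolerance = 0.011)
  expect_equal(res$p_value, 0.452, tolerance = 0.002)
  expect_gt(res$intercept_p, 0.05)   # no evidence of unbalanced pleiotropy
})

test_that("exact linearity recovers a zero intercept and the true slope", {
  bx <- c(0.02, 0.03, 0.05, 0.08, 0.04)
  v <- make_variants(bx = bx, by = -0.4 * bx)
  res <- mr_egger(v)
  expect_equal(res$beta, -0.4, tolerance = 1e-10)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  # with a planted intercept: y = a + c x
  v2 <- make_variants(bx = bx, by = 0.01 - 0.4 * bx)
  res2 <- mr_egger(v2)
  expect_equal(res2$beta, -0.4, tolerance = 1e-10)
  expect_equal(res2$intercept, 0.01, tolerance = 1e-12)
})

test_that("two variants give a saturated Egger fit with zero residual", {
  res <- mr_egger(six_variants()[1:2, ])
  expect_equal(res$q_stat, 0, tolerance = 1e-20)
  expect_error(mr_egger(six_variants()[1L, ]), "at least two")
})

test_that("Egger refuses unharmonized input", {
  v <- six_variants()
  v$beta_exposure[4L] <- -v$beta_exposure[4L]
  expect_error(mr_egger(v), "harmonize")
})

test_that("Egger intercept is unbiased under a shared causal slope", {
  # no-pleiotropy generative model at the summary level: y_k = c*x_k + e_k
  set.seed(2025)
  n_rep <- 1500L
  bx <- six_variants()$beta_exposure
  sy <- six_variants()$se_outcome
  ints <- vapply(seq_len(n_rep), function(i) {
    v <- make_variants(bx = bx, by = -0.2 * bx + rnorm(6, 0, sy), sy = sy)
    mr_egger(v)$intercept
  }, numeric(1L))
  mc_se <- sd(ints) / sqrt(n_rep)
  expect_lt(abs(mean(ints)), 2 * mc_se + 1e-12)
})
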