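test_that("simulated visits carry the model-implied correlation", {
  set.seed(21)
  d <- simulate_cohort(sim_spec(n = 20000, t = 3, maf = 0.3, beta = 0,
                                sigma_c2 = 0.4, sigma_e2 = 0.6))
  expect_lt(abs(cor(d$Y[, 1], d$Y[, 2]) - 0.4), 0.015)
  expect_lt(abs(cor(d$Y[, 1], d$Y[, 3]) - 0.4), 0.015)
  # within-subject covariance matches sigma_c2 J + sigma_e2 I
  emp <- cov(d$Y)
  model <- 0.4 + diag(0.6, 3)
  expect_lt(max(abs(emp - model)), 3 * sqrt(2 / 20000) * 1.5)
})

test_that("single-visit variance decomposes as 2 beta^2 p(1-p) + noise", {
  set.seed(22)
  beta <- 0.5; p <- 0.3
  d <- simulate_cohort(sim_spec(n = 50000, t = 1, maf = p, beta = beta,
                                sigma_c2 = 0.4, sigma_e2 = 0.6))
  expect_equal(var(d$Y[, 1]), 2 * beta^2 * p * (1 - p) + 1,
               tolerance = 0.02)
})

test_that("the noise-free cohort is exactly deterministic in the dosage", {
  set.seed(23)
  d <- simulate_cohort(sim_spec(n = 50, t = 3, maf = 0.4, beta = 1,
                                sigma_c2 = 0, sigma_e2 = 0,
                                alpha = c(intercept = 2)))
  expect_equal(d$Y, tcrossprod(2 + d$snp, rep(1, 3)), ignore_attr = TRUE)
})

test_that("the same seed reproduces the cohort bit for bit", {
  spec <- sim_spec(n = 200, t = 3, maf = 0.2, beta = 0.1, sigma_g2 = 0.1,
                   dropout = c(1, 0.8, 0.6))
  set.seed(99); d1 <- simulate_cohort(spec)
  set.seed(99); d2 <- simulate_cohort(spec)
  expect_identical(d1, d2)
  set.seed(100); d3 <- simulate_cohort(spec)
  expect_false(identical(d1$Y, d3$Y))
})

test_that("monotone dropout yields prefix masks at the requested rates", {
  set.seed(24)
  d <- simulate_cohort(sim_spec(n = 20000, t = 3, maf = 0.3,
                                dropout = "kare"))
  # observed visits form a prefix
  expect_true(all(d$mask[, 2] >= d$mask[, 3]))
  expect_true(all(d$mask[, 1]))
  frac <- colMeans(d$mask)
  expect_equal(frac, c(1, 7568 / 8842, 6675 / 8842), tolerance = 0.015)
  expect_error(sim_spec(n = 10, t = 3, maf = 0.3, dropout = c(1, 0.5, 0.7)),
               "non-increasing")
})

test_that("the polygenic shared factor induces cross-subject covariance", {
  # cov(Y_i, Y_j) between distinct subjects = kinship_offdiag * sigma_g2;
  # estimated across independent replicate cohorts of two subjects
  set.seed(25)
  spec <- sim_spec(n = 2, t = 1, maf = 0.3, beta = 0, sigma_g2 = 0.5,
                   sigma_c2 = 0.25, sigma_e2 = 0.25, kinship_offdiag = 0.4)
  pairs <- t(replicate(4000, simulate_cohort(spec)$Y[, 1]))
  expect_lt(abs(cov(pairs[, 1], pairs[, 2]) - 0.4 * 0.5), 0.05)
  expect_lt(abs(var(pairs[, 1]) - 1), 0.08)
})

test_that("Monte-Carlo power is calibrated under the null and monotone", {
  set.seed(26)
  null_mc <- monte_carlo_power(sim_spec(n = 300, t = 3, maf = 0.3, beta = 0),
                               alpha = 0.05, replicates = 400)
  expect_lt(abs(null_mc$power - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_identical(null_mc$failed, 0L)

  set.seed(27)
  beta <- effect_size_from_q(0.02, 1, 0.3)
  p_small <- monte_carlo_power(sim_spec(n = 150, t = 3, maf = 0.3,
                                        beta = beta),
                               alpha = 1e-3, replicates = 150)$power
  p_large <- monte_carlo_power(sim_spec(n = 600, t = 3, maf = 0.3,
                                        beta = beta),
                               alpha = 1e-3, replicates = 150)$power
  expect_gt(p_large, p_small)
})

test_that("power decreases with the between-visit correlation", {
  set.seed(28)
  beta <- effect_size_from_q(0.02, 1, 0.3)
  p_lo <- monte_carlo_power(sim_spec(n = 250, t = 3, maf = 0.3, beta = beta,
                                     sigma_c2 = 0.0, sigma_e2 = 1.0),
                            alpha = 1e-3, replicates = 200)$power
  p_hi <- monte_carlo_power(sim_spec(n = 250, t = 3, maf = 0.3, beta = beta,
                                     sigma_c2 = 0.9, sigma_e2 = 0.1),
                            alpha = 1e-3, replicates = 200)$power
  expect_gt(p_lo, p_hi)
})

test_that("Monte-Carlo sample size agrees with the closed form", {
  # scaled-down design point so each probe stays cheap: alpha 1e-3,
  # q = 0.05, rho = 0.4, t = 3
  set.seed(29)
  beta <- effect_size_from_q(0.05, 1, 0.3)
  spec <- sim_spec(n = 100, t = 3, maf = 0.3, beta = beta,
                   sigma_c2 = 0.4, sigma_e2 = 0.6)
  res <- monte_carlo_sample_size(spec, alpha = 1e-3, target_power = 0.8,
                                 replicates = 300)
  analytic <- analytic_sample_size(design_spec(3, 0.4, 1e-3, 0.8,
                                               q = 0.05))$n
  expect_lt(abs(res$n - analytic) / analytic, 0.2)
  expect_true(all(diff(res$probed$n) > 0))
})
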