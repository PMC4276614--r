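# Discovery (two-sided) and replication (one-sided) p-values for the five
# replicated sex-by-SNP interactions, with the published combined values;
# cohort sizes 8841 (discovery) and 3703 (replication).
published_rows <- data.frame(
  label = c("rs2074356/HDL", "rs11066280/HDL", "rs2074356/logAST",
            "rs11066280/logAST", "rs12229654/logAST"),
  p_discovery = c(4.46e-9, 1.06e-9, 5.82e-8, 8.25e-12, 3.24e-11),
  p_replication = c(3.58e-1, 2.184e-1, 4.86e-2, 1.23e-2, 7.42e-3),
  fisher = c(3.39e-8, 5.37e-9, 5.86e-8, 3.13e-12, 7.22e-12),
  liptak = c(2.52e-7, 2.52e-8, 4.41e-8, 3.10e-12, 4.96e-12))
cohort_n <- c(8841, 3703)

test_that("direction-aware one-sided p-values fold at 0.5", {
  expect_equal(one_sided_p(1, 0.05, +1), 0.025)
  expect_equal(one_sided_p(-1, 0.05, +1), 0.975)
  expect_equal(one_sided_p(0, 0.05, +1), 0.5)
  expect_equal(one_sided_p(c(-2, 2), c(0.1, 0.1), -1), c(0.05, 0.95))
  expect_error(one_sided_p(1, 0, +1), "p-values")
  expect_error(one_sided_p(1, 0.5, 0), "non-zero")
})

test_that("Fisher's method reproduces the published combined p-values", {
  for (i in seq_len(nrow(published_rows))) {
    comb <- fisher_combine(c(published_rows$p_discovery[i],
                             published_rows$p_replication[i]))
    expect_equal(comb$p, published_rows$fisher[i], tolerance = 5e-3)
  }
  expect_equal(fisher_combine(c(1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1))$p, 1)
  comb <- fisher_combine(c(0.05, 0.05))
  expect_equal(comb$statistic, 11.98293, tolerance = 1e-5)
  # closed-form 4-df survival: (1 + x/2) exp(-x/2)
  x <- comb$statistic
  expect_equal(comb$p, (1 + x / 2) * exp(-x / 2), tolerance = 1e-12)
  expect_equal(comb$p, 0.01747, tolerance = 1e-3)
  expect_error(fisher_combine(c(0, 0.1)), "positive")
})

test_that("Liptak's weighted-Z method reproduces the published values", {
  for (i in seq_len(nrow(published_rows))) {
    comb <- liptak_combine(c(published_rows$p_discovery[i],
                             published_rows$p_replication[i]),
                           n = cohort_n)
    expect_equal(comb$p, published_rows$liptak[i], tolerance = 5e-3)
  }
  expect_equal(liptak_combine(c(0.5, 0.5), n = c(10, 10))$z, 0)
  expect_equal(liptak_combine(c(0.5, 0.5), n = c(10, 10))$p, 0.5)
  expect_error(liptak_combine(c(0.5, 1), n = c(10, 10)), "strictly")
  expect_error(liptak_combine(c(0.5, 0.5)), "weights")
})

test_that("both combinations are symmetric and Liptak reduces to Stouffer", {
  p <- c(0.01, 0.2, 0.7)
  expect_equal(fisher_combine(p)$p, fisher_combine(rev(p))$p)
  expect_equal(liptak_combine(p, n = c(5, 5, 5))$p,
               liptak_combine(rev(p), n = c(5, 5, 5))$p)
  # equal weights = unweighted Stouffer
  z <- sum(qnorm(1 - p)) / sqrt(3)
  expect_equal(liptak_combine(p, weights = c(1, 1, 1))$z, z)
  # monotone decreasing in each component p-value
  base <- liptak_combine(c(0.1, 0.3), n = c(100, 50))$p
  expect_lt(liptak_combine(c(0.05, 0.3), n = c(100, 50))$p, base)
  expect_lt(liptak_combine(c(0.1, 0.2), n = c(100, 50))$p, base)
})

test_that("combined p-values are uniform under the null", {
  set.seed(61)
  pairs <- matrix(runif(2 * 10000), ncol = 2)
  fp <- apply(pairs, 1, function(p) fisher_combine(p)$p)
  lp <- apply(pairs, 1, function(p) liptak_combine(p, n = c(70, 30))$p)
  expect_gt(suppressWarnings(ks.test(fp, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(lp, "punif"))$p.value, 0.01)
})

test_that("combine_cohorts returns both methods coherently", {
  res <- combine_cohorts(c(1e-6, 0.02), n = cohort_n)
  expect_equal(res$fisher$p, fisher_combine(c(1e-6, 0.02))$p)
  expect_equal(res$liptak$p, liptak_combine(c(1e-6, 0.02), n = cohort_n)$p)
})
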