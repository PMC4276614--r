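make_toy_data <- function(n = 8, t = 3, seed = 5, missing = FALSE) {
  set.seed(seed)
  Y <- matrix(rnorm(n * t), n, t)
  mask <- matrix(TRUE, n, t)
  if (missing) mask[seq(2, n, by = 3), t] <- FALSE
  Y[!mask] <- NA
  Z <- cbind(intercept = 1, sex = rbinom(n, 1, 0.5),
             age = rnorm(n, 50, 8))
  longitudinal_dataset(seq_len(n), Y, mask, Z = Z,
                       snp = rbinom(n, 2, 0.3), time_offsets = 2 * (0:(t - 1)))
}

test_that("GLS with known covariance matches the dense stacked oracle", {
  for (missing in c(FALSE, TRUE)) {
    d <- make_toy_data(n = 9, t = 3, seed = 31 + missing, missing = missing)
    Sig <- matrix(c(1.0, 0.5, 0.3,
                    0.5, 1.5, 0.6,
                    0.3, 0.6, 2.0), 3)
    fit <- fit_gls_longitudinal(d, sigma = Sig)
    U <- cbind(d$Z, SNP = d$snp)
    V <- matrix(1, nrow(U), 1)
    oracle <- dense_gls_oracle(d$Y, d$mask, U, V, d$time_offsets, Sig)
    expect_equal(fit$coefficients$estimate, oracle$coef,
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(fit$coefficients$se, sqrt(diag(oracle$vcov)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("GLS with a spherical covariance equals stacked OLS", {
  d <- make_toy_data(n = 30, t = 3, seed = 33, missing = TRUE)
  fit <- fit_gls_longitudinal(d, sigma = diag(3))
  # stacked long-format OLS with the same design
  obs <- which(d$mask, arr.ind = TRUE)
  y <- d$Y[obs]
  df <- data.frame(y = y, sex = d$Z[obs[, 1], "sex"],
                   age = d$Z[obs[, 1], "age"], snp = d$snp[obs[, 1]],
                   time = d$time_offsets[obs[, 2]])
  ols <- lm(y ~ sex + age + snp + time, data = df)
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols)[c("(Intercept)", "sex", "age", "snp",
                                  "time")]),
               tolerance = 1e-10)
})

test_that("a single visit reduces the GLS to cross-sectional OLS", {
  d <- make_toy_data(n = 40, t = 3, seed = 34)
  f_cross <- fit_ols_cross_sectional(d)
  d1 <- longitudinal_dataset(d$ids, d$Y[, 1, drop = FALSE], Z = d$Z,
                             snp = d$snp, time_offsets = 0)
  f_long1 <- fit_gls_longitudinal(d1)
  expect_equal(f_cross$coefficients, f_long1$coefficients)

  ols <- lm(d$Y[, 1] ~ d$Z[, "sex"] + d$Z[, "age"] + d$snp)
  expect_equal(f_cross$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
  # standard errors use the ML variance (residual SS / n)
  n <- nrow(d$Y); p <- 4
  expect_equal(f_cross$coefficients$se,
               unname(sqrt(diag(vcov(ols))) * sqrt((n - p) / n)),
               tolerance = 1e-10)
})

test_that("a noise-free cross-sectional fit recovers beta exactly", {
  set.seed(35)
  d <- simulate_cohort(sim_spec(n = 60, t = 1, maf = 0.4, beta = 0.73,
                                sigma_c2 = 0, sigma_e2 = 0))
  # zero residual noise makes the estimated covariance singular, so the
  # ridge repair is expected to fire on every iteration
  w <- capture_warnings(fit <- fit_ols_cross_sectional(d))
  expect_gt(length(w), 0)
  expect_true(all(grepl("positive definite", w)))
  expect_equal(coef_term(fit, "SNP")$estimate, 0.73, tolerance = 1e-10)
})

test_that("the estimated covariance converges to the generating truth", {
  set.seed(36)
  d <- simulate_cohort(sim_spec(n = 20000, t = 3, maf = 0.3, beta = 0.1,
                                sigma_c2 = 0.4, sigma_e2 = 0.6))
  fit <- fit_gls_longitudinal(d)
  truth <- 0.4 + diag(0.6, 3)
  expect_lt(max(abs(fit$sigma - truth)), 3 * sqrt(2 / 20000) * 1.5)
  expect_true(fit$converged)
})

test_that("interval estimates cover the generating effect", {
  set.seed(37)
  covered <- logical(200)
  for (r in seq_along(covered)) {
    d <- simulate_cohort(sim_spec(n = 400, t = 3, maf = 0.3, beta = 0.1,
                                  sigma_c2 = 0.4, sigma_e2 = 0.6,
                                  dropout = c(1, 0.85, 0.75)))
    row <- coef_term(fit_gls_longitudinal(d), "SNP")
    covered[r] <- abs(row$estimate - 0.1) <= qnorm(0.975) * row$se
  }
  expect_gte(mean(covered), 0.90)
})

test_that("cross-sectional null p-values are uniform", {
  set.seed(38)
  n <- 300; m <- 2000
  d <- simulate_cohort(sim_spec(n = n, t = 1, maf = 0.3, beta = 0))
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  scan <- gwas_scan(d, G, model = "cross")
  frac <- mean(scan$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("a simulated sex-by-SNP interaction is recovered", {
  set.seed(39)
  d <- simulate_cohort(sim_spec(n = 5000, t = 3, maf = 0.3, beta = 0.1,
                                sigma_c2 = 0.4, sigma_e2 = 0.6,
                                sex_snp_effect = 0.08))
  fit <- fit_interaction(d, environment = "sex", model = "longitudinal")
  row <- coef_term(fit, "sex:SNP")
  expect_lt(abs(row$estimate - 0.08), 2 * row$se)
  # the main SNP effect is retained in the design
  expect_equal(nrow(coef_term(fit, "SNP")), 1)
})

test_that("interaction with a constant environment is rejected", {
  d <- make_toy_data(n = 20, t = 3, seed = 40)
  d$Z[, "sex"] <- 1  # all-male cohort
  expect_error(fit_interaction(d, environment = "sex"), "constant")
  expect_error(fit_interaction(d, environment = "time", model = "cross"),
               "longitudinal")
})

test_that("a time-by-SNP slope is estimated in the longitudinal model", {
  set.seed(41)
  d <- simulate_cohort(sim_spec(n = 3000, t = 3, maf = 0.3, beta = 0.1,
                                sigma_c2 = 0.4, sigma_e2 = 0.6,
                                time_snp_effect = 0.05))
  fit <- fit_interaction(d, environment = "time", model = "longitudinal")
  row <- coef_term(fit, "time:SNP")
  expect_lt(abs(row$estimate - 0.05), 2 * row$se)
})

test_that("Wald z is invariant to affine rescaling of covariates", {
  d <- make_toy_data(n = 50, t = 3, seed = 42, missing = TRUE)
  f1 <- fit_gls_longitudinal(d)
  Z2 <- d$Z
  Z2[, "age"] <- (Z2[, "age"] - 50) / 10
  f2 <- fit_gls_longitudinal(d, covariates = Z2)
  expect_equal(coef_term(f1, "SNP")$z, coef_term(f2, "SNP")$z,
               tolerance = 1e-8)
  expect_equal(coef_term(f1, "age")$z, coef_term(f2, "age")$z,
               tolerance = 1e-8)
})

test_that("longitudinal analysis outranks cross-sectional on average", {
  set.seed(43)
  reps <- 200
  lp <- cp <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- simulate_cohort(sim_spec(n = 250, t = 3, maf = 0.3, beta = 0.15,
                                  sigma_c2 = 0.4, sigma_e2 = 0.6))
    lp[r] <- coef_term(fit_gls_longitudinal(d), "SNP")$p
    cp[r] <- coef_term(fit_ols_cross_sectional(d), "SNP")$p
  }
  expect_lt(mean(log(lp)), mean(log(cp)))
})

test_that("build_covariates assembles the phenotype-specific design", {
  tab <- data.frame(sex = c(0, 1, 1), age = c(45, 52, 63),
                    weight = c(60, 72, 81))
  Z_hdl <- build_covariates(tab, "HDL")
  expect_identical(colnames(Z_hdl), c("intercept", "sex", "age", "age2"))
  Z_glu <- build_covariates(tab, "GLU0")
  expect_identical(colnames(Z_glu),
                   c("intercept", "sex", "age", "age2", "weight"))
  expect_equal(Z_hdl[, "age2"], tab$age^2)
  expect_error(build_covariates(tab[, "sex", drop = FALSE], "HDL"),
               "age")
  tab$age <- 50
  expect_error(build_covariates(tab, "HDL"), "constant")
  tab2 <- data.frame(sex = c(0, NA), age = c(45, 52))
  expect_error(build_covariates(tab2, "HDL"), "sex")
})

test_that("gwas_scan flags the planted causal SNP and tolerates failures", {
  set.seed(44)
  n <- 1500
  beta <- effect_size_from_q(0.01, 1, 0.3)
  d <- simulate_cohort(sim_spec(n = n, t = 3, maf = 0.3, beta = beta,
                                sigma_c2 = 0.4, sigma_e2 = 0.6))
  G <- cbind(matrix(rbinom(n * 30, 2, 0.3), n, 30), causal = d$snp,
             mono = rep(0, n))
  colnames(G)[1:30] <- paste0("null", 1:30)
  scan <- gwas_scan(d, G, model = "longitudinal")
  expect_identical(scan$snp[which.min(scan$p)], "causal")
  expect_identical(scan$note[scan$snp == "mono"], "monomorphic")
  expect_true(is.na(scan$p[scan$snp == "mono"]))

  empty <- gwas_scan(d, matrix(numeric(0), n, 0), model = "cross")
  expect_identical(nrow(empty), 0L)
})
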