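#' Specification of a synthetic longitudinal cohort
#'
#' Parameters of the generating model for repeated phenotype measurements
#' `Y_ij = Z_i alpha + X_i beta + g_i + c_i + eta w_j + e_ij`,
#' with genotype dosage `X_i` drawn from Hardy-Weinberg frequencies at
#' allele frequency `maf`, a subject-level random intercept
#' `c_i ~ N(0, sigma_c2)`, independent visit noise `e_ij ~ N(0, sigma_e2)`,
#' and an optional polygenic effect `g` drawn jointly across subjects with
#' covariance `sigma_g2 * Phi`, `Phi` compound symmetric with off-diagonal
#' `kinship_offdiag` (genetically remote relatives at the default 0.1).
#' When `sigma_g2 = 0` the within-subject correlation is compound symmetric
#' with intraclass correlation `sigma_c2 / (sigma_c2 + sigma_e2)`.
#'
#' @param n Number of subjects.
#' @param t Visits per subject.
#' @param maf Minor-allele frequency of the causal SNP.
#' @param beta Per-allele effect on the phenotype.
#' @param sigma_g2,sigma_c2,sigma_e2 Polygenic, subject-level and residual
#'   variance components (each >= 0).
#' @param kinship_offdiag Common off-diagonal of the kinship matrix Phi
#'   (default 0.1); must lie in \[0, 1\] for the shared-factor construction.
#' @param dropout Optional per-visit retention fractions (non-increasing,
#'   first entry 1): each subject's observed visits form a prefix, and the
#'   marginal fraction retained at visit j equals `dropout[j]`
#'   (missingness completely at random). `dropout = "kare"` uses the
#'   three-visit retention pattern 1, 0.856, 0.755 of a large biennial
#'   population cohort (8842, 7568 and 6675 subjects).
#' @param time_offsets Visit times; default `2 * (0:(t-1))` years.
#' @param alpha Named coefficients for the generated subject-level
#'   covariates `intercept`, `sex` (Bernoulli 0.5) and `age`
#'   (Normal(52, 8.9), baseline years); default all zero.
#' @param eta Linear visit-time (aging) effect; default 0.
#' @param sex_snp_effect,time_snp_effect Optional interaction effects added
#'   to the generating model; default 0.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n, t, maf, beta = 0, sigma_g2 = 0, sigma_c2 = 0.4,
                     sigma_e2 = 0.6, kinship_offdiag = 0.1, dropout = NULL,
                     time_offsets = NULL,
                     alpha = c(intercept = 0, sex = 0, age = 0),
                     eta = 0, sex_snp_effect = 0, time_snp_effect = 0) {
  if (n < 1 || t < 1) stop("n and t must be >= 1", call. = FALSE)
  if (maf < 0 || maf > 1) stop("maf must lie in [0, 1]", call. = FALSE)
  if (sigma_g2 < 0 || sigma_c2 < 0 || sigma_e2 < 0)
    stop("variance components must be non-negative", call. = FALSE)
  if (kinship_offdiag < 0 || kinship_offdiag > 1)
    stop("kinship_offdiag must lie in [0, 1]", call. = FALSE)
  if (identical(dropout, "kare")) dropout <- c(1, 7568, 6675) / c(1, 8842, 8842)
  if (!is.null(dropout)) {
    if (length(dropout) != t)
      stop("dropout must give one retention fraction per visit", call. = FALSE)
    if (abs(dropout[1] - 1) > 1e-12)
      stop("baseline retention must be 1", call. = FALSE)
    if (any(diff(dropout) > 1e-12))
      stop("retention fractions must be non-increasing (monotone dropout)",
           call. = FALSE)
  }
  if (is.null(time_offsets)) time_offsets <- 2 * (seq_len(t) - 1)
  a <- c(intercept = 0, sex = 0, age = 0)
  a[names(alpha)] <- alpha
  structure(list(n = as.integer(n), t = as.integer(t), maf = maf,
                 beta = beta, sigma_g2 = sigma_g2, sigma_c2 = sigma_c2,
                 sigma_e2 = sigma_e2, kinship_offdiag = kinship_offdiag,
                 dropout = dropout, time_offsets = time_offsets, alpha = a,
                 eta = eta, sex_snp_effect = sex_snp_effect,
                 time_snp_effect = time_snp_effect),
            class = "sim_spec")
}

#' Simulate a longitudinal cohort
#'
#' Draws a cohort from the model described in [sim_spec()]. The polygenic
#' vector is generated through its shared-factor representation
#' `g_i = sigma_g (sqrt(a) u + sqrt(1-a) v_i)` with a common `u` and
#' independent `v_i`, which realises the compound-symmetric covariance
#' `sigma_g2 * Phi` without forming or factoring an n x n matrix.
#'
#' @param spec A [sim_spec()].
#' @return A [longitudinal_dataset()] with the causal dosages in `$snp`
#'   and covariates `intercept`, `sex`, `age` in `$Z`.
#' @examples
#' set.seed(42)
#' d <- simulate_cohort(sim_spec(n = 100, t = 3, maf = 0.3, beta = 0.1))
#' visit_counts(d)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n; t <- spec$t
  x <- stats::rbinom(n, 2, spec$maf)
  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::rnorm(n, 52, 8.9)
  Z <- cbind(intercept = 1, sex = sex, age = age)
  subject_mean <- drop(Z %*% spec$alpha) + x * spec$beta +
    spec$sex_snp_effect * sex * x
  if (spec$sigma_c2 > 0)
    subject_mean <- subject_mean + stats::rnorm(n, 0, sqrt(spec$sigma_c2))
  if (spec$sigma_g2 > 0) {
    a <- spec$kinship_offdiag
    g <- sqrt(spec$sigma_g2) *
      (sqrt(a) * stats::rnorm(1) + sqrt(1 - a) * stats::rnorm(n))
    subject_mean <- subject_mean + g
  }
  w <- spec$time_offsets
  slope <- spec$eta + spec$time_snp_effect * x
  Y <- tcrossprod(subject_mean, rep(1, t)) + tcrossprod(slope, w)
  if (spec$sigma_e2 > 0)
    Y <- Y + matrix(stats::rnorm(n * t, 0, sqrt(spec$sigma_e2)), n, t)
  mask <- matrix(TRUE, n, t)
  if (!is.null(spec$dropout) && t > 1) {
    u <- stats::runif(n)
    for (j in 2:t) mask[, j] <- u <= spec$dropout[j]
  }
  Y[!mask] <- NA_real_
  longitudinal_dataset(ids = paste0("S", seq_len(n)), Y = Y, mask = mask,
                       Z = Z, snp = x, time_offsets = w)
}

# Fit one simulated replicate and return the SNP Wald p-value. The
# "gls_independent" analysis is the repeated-measures GLS treating subjects
# as independent (the standard association model); "gls_whitened" whitens
# by the known total covariance including the polygenic term, using the
# Sherman-Morrison identity for the rank-one shared factor so no n x n
# matrix is formed.
replicate_pvalue <- function(spec, analysis) {
  d <- simulate_cohort(spec)
  if (analysis == "gls_independent") {
    fit <- fit_gls_longitudinal(d, covariates = d$Z[, "intercept",
                                                    drop = FALSE])
    return(coef_term(fit, "SNP")$p)
  }
  # Whitened analysis: total covariance of the stacked data is
  # I_n (x) Sigma0 + c 1 1' with Sigma0 the within-subject covariance
  # including the independent polygenic part and c = a * sigma_g2.
  t <- spec$t
  sigma0 <- (spec$sigma_c2 + spec$sigma_g2 * (1 - spec$kinship_offdiag)) *
    matrix(1, t, t) + diag(spec$sigma_e2, t)
  cshare <- spec$kinship_offdiag * spec$sigma_g2
  U <- cbind(intercept = 1, SNP = d$snp)
  V <- matrix(1, nrow(U), 1, dimnames = list(NULL, "time"))
  Y0 <- d$Y; Y0[!d$mask] <- 0
  w <- d$time_offsets
  key <- as.vector(d$mask %*% 2^(seq_len(t) - 1))
  groups <- split(seq_len(nrow(U)), key)
  p <- ncol(U) + 1
  A <- matrix(0, p, p); bvec <- numeric(p); uvec <- numeric(p)
  svec <- 0; qscal <- 0
  for (ix in groups) {
    o <- which(d$mask[ix[1], ])
    Wo <- chol2inv(chol(sigma0[o, o, drop = FALSE]))
    ones <- rep(1, length(o)); wo <- w[o]
    Wo1 <- Wo %*% ones; Wow <- Wo %*% wo
    a1 <- sum(Wo1); b1 <- sum(wo * Wo1); c1 <- sum(wo * Wow)
    Us <- U[ix, , drop = FALSE]; Vs <- V[ix, , drop = FALSE]
    Ys <- Y0[ix, o, drop = FALSE]
    y1 <- Ys %*% Wo1; yw <- Ys %*% Wow
    A[1:2, 1:2] <- A[1:2, 1:2] + crossprod(Us) * a1
    A[1:2, 3] <- A[1:2, 3] + crossprod(Us, Vs) * b1
    A[3, 3] <- A[3, 3] + sum(Vs^2) * c1
    bvec[1:2] <- bvec[1:2] + crossprod(Us, y1)
    bvec[3] <- bvec[3] + sum(Vs * yw)
    uvec[1:2] <- uvec[1:2] + colSums(Us) * a1
    uvec[3] <- uvec[3] + sum(Vs) * b1
    svec <- svec + sum(y1)
    qscal <- qscal + length(ix) * a1
  }
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  shrink <- cshare / (1 + cshare * qscal)
  A <- A - shrink * tcrossprod(uvec)
  bvec <- bvec - shrink * uvec * svec
  vcov <- chol2inv(chol(A))
  est <- drop(vcov %*% bvec)
  z <- est[2] / sqrt(vcov[2, 2])
  2 * pnorm(-abs(z))
}

#' Monte-Carlo power of the repeated-measures association test
#'
#' Simulates replicate cohorts from a [sim_spec()] and reports the fraction
#' in which the Wald test of the SNP coefficient rejects at level `alpha`.
#'
#' @param spec A [sim_spec()].
#' @param alpha Two-sided significance level.
#' @param replicates Number of simulated cohorts.
#' @param analysis `"gls_independent"` fits the repeated-measures GLS that
#'   treats subjects as independent (the standard association analysis);
#'   `"gls_whitened"` whitens by the known total covariance including the
#'   polygenic component.
#' @return A list with `power`, its binomial standard error `se`,
#'   `replicates`, the number of `failed` replicates (excluded from the
#'   denominator) and the analysis used.
#' @examples
#' set.seed(7)
#' monte_carlo_power(sim_spec(n = 300, t = 3, maf = 0.3, beta = 0.25),
#'                   alpha = 0.05, replicates = 50)
#' @export
monte_carlo_power <- function(spec, alpha, replicates = 400,
                              analysis = c("gls_independent",
                                           "gls_whitened")) {
  stopifnot(inherits(spec, "sim_spec"))
  analysis <- match.arg(analysis)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  pvals <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    pvals[r] <- tryCatch(replicate_pvalue(spec, analysis),
                         error = function(e) NA_real_)
  }
  ok <- !is.na(pvals)
  power <- mean(pvals[ok] < alpha)
  list(power = power,
       se = sqrt(power * (1 - power) / sum(ok)),
       replicates = replicates, failed = sum(!ok), analysis = analysis)
}

#' Monte-Carlo required sample size
#'
#' Finds the smallest cohort size on a bisection grid whose simulated power
#' reaches the target. Used when the closed form does not apply, e.g. in
#' the presence of a polygenic component. The analytic sample size for the
#' matching no-polygenic design seeds the initial bracket.
#'
#' @param spec A [sim_spec()]; its `n` is ignored.
#' @param alpha Significance level.
#' @param target_power Target power in (0, 1).
#' @param replicates Replicates per probed sample size.
#' @param analysis Passed to [monte_carlo_power()].
#' @return A list with `n` (the selected size), `probed` (a data frame of
#'   the sizes probed with their power estimates), and `analysis`.
#' @export
monte_carlo_sample_size <- function(spec, alpha, target_power,
                                    replicates = 200,
                                    analysis = c("gls_independent",
                                                 "gls_whitened")) {
  stopifnot(inherits(spec, "sim_spec"))
  analysis <- match.arg(analysis)
  if (target_power <= 0 || target_power >= 1)
    stop("target power must lie in (0, 1)", call. = FALSE)
  rho_eff <- (spec$sigma_c2 + spec$sigma_g2) /
    (spec$sigma_c2 + spec$sigma_g2 + spec$sigma_e2)
  sigma_p2 <- spec$sigma_g2 + spec$sigma_c2 + spec$sigma_e2
  ds <- design_spec(spec$t, rho_eff, alpha, target_power, beta = spec$beta,
                    maf = spec$maf, sigma_p2 = sigma_p2)
  n_mid <- analytic_sample_size(ds)$n
  if (!is.finite(n_mid)) stop("zero effect: sample size is infinite",
                              call. = FALSE)
  step <- max(round(0.01 * n_mid), 10)
  power_at <- function(n) {
    s <- spec; s$n <- as.integer(max(n, 2))
    monte_carlo_power(s, alpha, replicates, analysis)$power
  }
  probed_n <- integer(0); probed_p <- numeric(0)
  probe <- function(n) {
    pw <- power_at(n)
    probed_n <<- c(probed_n, n); probed_p <<- c(probed_p, pw)
    pw
  }
  # establish a bracket [lo, hi] with power(lo) < target <= power(hi)
  p_mid <- probe(n_mid)
  if (p_mid >= target_power) {
    hi <- n_mid
    lo <- step
    repeat {
      cand <- max(round(hi * 0.75), step)
      if (cand >= hi) break
      if (probe(cand) < target_power) { lo <- cand; break }
      hi <- cand
      if (cand == step) break
    }
  } else {
    lo <- n_mid; hi <- n_mid
    grew <- FALSE
    for (i in 1:8) {
      hi <- round(hi * 1.5)
      if (probe(hi) >= target_power) { grew <- TRUE; break }
      lo <- hi
    }
    if (!grew)
      warning("target power not reached within the search bracket; ",
              "returning the upper bracket")
  }
  while (hi - lo > step) {
    mid <- round((lo + hi) / 2)
    if (probe(mid) >= target_power) hi <- mid else lo <- mid
  }
  ord <- order(probed_n)
  list(n = hi,
       probed = data.frame(n = probed_n, power = probed_p)[ord, ],
       analysis = analysis)
}
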