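#' Study design for a repeated-measures association test
#'
#' Bundles the design parameters used by the closed-form sample-size and
#' power calculations: number of visits `t`, common between-visit
#' correlation `rho`, two-sided significance level `alpha`, target power,
#' and the effect size given either as the variance-explained fraction `q`
#' (in which case the result does not depend on the allele frequency) or as
#' an explicit `(beta, maf)` pair.
#'
#' @param t Number of visits per subject (integer >= 1).
#' @param rho Correlation between phenotype measurements at two visits on
#'   the same subject, in \[0, 1\].
#' @param alpha Two-sided significance level, e.g. `1e-8` for genome-wide
#'   significance.
#' @param power Target power, in (0, 1).
#' @param q Fraction of phenotypic variance explained by the SNP. Under
#'   this parameterization `K * beta^2 = sigma_p2 * q / (1 - q)` and the
#'   sample size is free of the minor-allele frequency.
#' @param beta Per-allele effect size; used with `maf` when `q` is `NULL`.
#' @param maf Minor-allele frequency for the explicit-effect
#'   parameterization (Hardy-Weinberg genotype frequencies assumed).
#' @param sigma_p2 Phenotypic variance not attributable to the SNP (the sum
#'   of the polygenic, subject-level and residual components; default 1,
#'   the normalized scale).
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(t = 3, rho = 0.4, alpha = 1e-8, power = 0.8, q = 0.005)
#' @export
design_spec <- function(t, rho, alpha, power, q = NULL, beta = NULL,
                        maf = NULL, sigma_p2 = 1) {
  t <- as.integer(t)
  if (is.na(t) || t < 1) stop("t must be an integer >= 1", call. = FALSE)
  if (!is.finite(rho) || rho < 0 || rho > 1)
    stop("rho must lie in [0, 1]", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is.finite(power) || power <= 0 || power >= 1)
    stop("power must lie in (0, 1)", call. = FALSE)
  if (!is.finite(sigma_p2) || sigma_p2 <= 0)
    stop("sigma_p2 must be positive", call. = FALSE)
  if (is.null(q) && (is.null(beta) || is.null(maf)))
    stop("supply either q (variance explained) or both beta and maf",
         call. = FALSE)
  if (!is.null(q) && (!is.finite(q) || q < 0 || q >= 1))
    stop("q must lie in [0, 1)", call. = FALSE)
  structure(list(t = t, rho = rho, alpha = alpha, power = power, q = q,
                 beta = beta, maf = maf, sigma_p2 = sigma_p2),
            class = "design_spec")
}

# K * beta^2, the per-subject-per-visit information scale of the design.
# Under the variance-explained parameterization this is sigma_p2 * q/(1-q),
# independent of MAF; with an explicit (beta, maf) pair it is computed from
# the HWE genotype variance.
kbeta2 <- function(spec) {
  if (!is.null(spec$q)) {
    spec$sigma_p2 * spec$q / (1 - spec$q)
  } else {
    k_statistic(genotype_dist_hwe(spec$maf)) * spec$beta^2
  }
}

#' Analytic sample size for a repeated-measures association design
#'
#' Closed-form number of subjects required for a Wald test of the SNP
#' effect to reach the target power at a two-sided level `alpha`:
#'
#' n = (z_(1-alpha/2) + z_(power))^2 * sigma_p2 / (K beta^2) *
#'     (1 + (t - 1) rho) / t
#'
#' where K is the variance of the additively coded genotype. The design
#' factor (1 + (t-1) rho)/t quantifies the efficiency gain of `t`
#' correlated visits over a single visit; at rho = 1 repeated visits carry
#' no extra information and the requirement equals the cross-sectional one.
#'
#' @param spec A [design_spec()].
#' @return A list of class `sample_size` with elements `n_exact` (the
#'   unrounded requirement), `n` (rounded to the nearest integer), and the
#'   design. A zero effect (or degenerate genotype) yields `Inf`.
#' @examples
#' analytic_sample_size(design_spec(3, 0.4, 1e-8, 0.8, q = 0.005))$n  # 5158
#' @export
analytic_sample_size <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  kb2 <- kbeta2(spec)
  zsum <- qnorm(1 - spec$alpha / 2) + qnorm(spec$power)
  if (kb2 <= 0) {
    n_exact <- Inf
  } else {
    n_exact <- zsum^2 * spec$sigma_p2 / kb2 *
      (1 + (spec$t - 1) * spec$rho) / spec$t
  }
  structure(list(n_exact = n_exact, n = round(n_exact), spec = spec),
            class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  cat(sprintf("Required sample size: n = %s (exact %.2f)\n",
              format(x$n), x$n_exact))
  cat(sprintf("  t = %d visits, rho = %g, alpha = %g, target power = %g\n",
              x$spec$t, x$spec$rho, x$spec$alpha, x$spec$power))
  invisible(x)
}

#' Power of the repeated-measures design at a given sample size
#'
#' Inverts the analytic sample-size formula:
#' power = Phi( sqrt(n * K beta^2 / sigma_p2 * t / (1 + (t-1) rho))
#'              - z_(1-alpha/2) ).
#' `analytic_sample_size()` and `power_at_n()` are mutual inverses on the
#' unrounded sample size.
#'
#' @param spec A [design_spec()] (its `power` element is ignored).
#' @param n Number of subjects (need not be an integer).
#' @return The power, in (0, 1).
#' @examples
#' spec <- design_spec(3, 0.4, 1e-8, 0.8, q = 0.005)
#' power_at_n(spec, 5158)
#' @export
power_at_n <- function(spec, n) {
  stopifnot(inherits(spec, "design_spec"))
  if (!is.finite(n) || n < 0) stop("n must be non-negative", call. = FALSE)
  kb2 <- kbeta2(spec)
  ncp <- sqrt(n * kb2 / spec$sigma_p2 * spec$t / (1 + (spec$t - 1) * spec$rho))
  pnorm(ncp - qnorm(1 - spec$alpha / 2))
}

#' Genotyping saved and phenotyping added by a repeated-measures design
#'
#' Compares the `t`-visit design against the cross-sectional (one-visit)
#' design at the same power, level and effect size. Fewer subjects need to
#' be genotyped, at the cost of extra phenotype measurements.
#'
#' @param spec A [design_spec()] with `t >= 2`.
#' @return A list with `n_long` (subjects for the t-visit design), `n_cross`
#'   (subjects for the one-visit design), `genotyping_saved`
#'   (`n_cross - n_long`) and `extra_phenotypes` (`t * n_long - n_cross`);
#'   each sample size is rounded to the nearest integer before differencing.
#' @examples
#' design_savings(design_spec(3, 0.4, 1e-8, 0.8, q = 0.005))
#' @export
design_savings <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$t < 2) stop("design_savings needs t >= 2", call. = FALSE)
  n_long <- analytic_sample_size(spec)$n
  spec1 <- spec
  spec1$t <- 1L
  n_cross <- analytic_sample_size(spec1)$n
  list(n_long = n_long, n_cross = n_cross,
       genotyping_saved = n_cross - n_long,
       extra_phenotypes = spec$t * n_long - n_cross)
}
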