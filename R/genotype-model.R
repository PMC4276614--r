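#' Trinomial genotype distribution
#'
#' Constructs the distribution of an additively coded biallelic genotype
#' X taking values 0, 1, 2 (copies of the minor allele) with probabilities
#' `pi1`, `pi2`, `pi3`.
#'
#' @param pi1,pi2,pi3 Genotype probabilities for 0, 1 and 2 copies of the
#'   coded (minor) allele. Must be non-negative and sum to 1.
#' @param maf Optional minor-allele frequency, recorded when the
#'   distribution arises from Hardy-Weinberg equilibrium.
#' @return An object of class `genotype_dist`: a list with elements
#'   `pi` (length-3 probability vector) and `maf` (may be `NA`).
#' @seealso [genotype_dist_hwe()], [k_statistic()]
#' @examples
#' genotype_dist(0.49, 0.42, 0.09)
#' @export
genotype_dist <- function(pi1, pi2, pi3, maf = NA_real_) {
  pi <- c(pi1, pi2, pi3)
  if (any(!is.finite(pi)) || any(pi < -1e-12) || any(pi > 1 + 1e-12))
    stop("genotype probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-12)
    stop("genotype probabilities must sum to 1 (got ", format(sum(pi)), ")",
         call. = FALSE)
  pi <- pmin(pmax(pi, 0), 1)
  structure(list(pi = pi, maf = maf), class = "genotype_dist")
}

#' Genotype distribution under Hardy-Weinberg equilibrium
#'
#' Genotype probabilities ((1-p)^2, 2p(1-p), p^2) for the additive coding
#' that counts copies of the allele with frequency `p`.
#'
#' @param p Allele frequency in \[0, 1\].
#' @return A [genotype_dist()] object with `maf = p`.
#' @examples
#' genotype_dist_hwe(0.3)  # pi = (0.49, 0.42, 0.09)
#' @export
genotype_dist_hwe <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("allele frequency must lie in [0, 1]", call. = FALSE)
  genotype_dist((1 - p)^2, 2 * p * (1 - p), p^2, maf = p)
}

#' @export
print.genotype_dist <- function(x, ...) {
  cat("Trinomial genotype distribution\n")
  cat(sprintf("  P(X = 0, 1, 2) = (%g, %g, %g)\n", x$pi[1], x$pi[2], x$pi[3]))
  if (!is.na(x$maf)) cat(sprintf("  HWE with allele frequency p = %g\n", x$maf))
  invisible(x)
}

#' The K statistic of a genotype distribution
#'
#' K = pi1 (pi2 + 2 pi3)^2 + pi2 (pi3 - pi1)^2 + pi3 (1 + pi1 - pi3)^2.
#' K equals the variance of the additively coded genotype under the
#' trinomial distribution; under Hardy-Weinberg equilibrium K = 2p(1-p).
#' It enters the denominator of the analytic sample-size formula.
#'
#' @param dist A [genotype_dist()] object.
#' @return The value of K (dimensionless).
#' @examples
#' k_statistic(genotype_dist_hwe(0.5))  # 0.5
#' @export
k_statistic <- function(dist) {
  stopifnot(inherits(dist, "genotype_dist"))
  p1 <- dist$pi[1]; p2 <- dist$pi[2]; p3 <- dist$pi[3]
  p1 * (p2 + 2 * p3)^2 + p2 * (p3 - p1)^2 + p3 * (1 + p1 - p3)^2
}

#' Allele effect size from the variance explained
#'
#' Solves for the per-allele effect beta such that the SNP explains a
#' fraction `q` of the total phenotypic variance,
#' 2 beta^2 p (1-p) / (2 beta^2 p (1-p) + residual_variance) = q,
#' i.e. 2 beta^2 p (1-p) = residual_variance * q / (1 - q),
#' assuming Hardy-Weinberg genotype frequencies at allele frequency `p`.
#'
#' @param q Fraction of phenotypic variance explained by the SNP, in \[0, 1).
#' @param residual_variance Variance not attributable to the SNP (the sum of
#'   the polygenic, subject-level and residual components). Default 1, the
#'   normalized scale.
#' @param p Allele frequency of the coded allele.
#' @return The non-negative effect size beta (phenotype units per allele).
#' @examples
#' effect_size_from_q(0.005, 1, 0.5)  # 0.10025
#' @export
effect_size_from_q <- function(q, residual_variance = 1, p) {
  if (!is.finite(q) || q < 0 || q >= 1)
    stop("variance explained q must lie in [0, 1)", call. = FALSE)
  if (!is.finite(residual_variance) || residual_variance <= 0)
    stop("residual variance must be positive", call. = FALSE)
  if (q == 0) return(0)
  if (p <= 0 || p >= 1)
    stop("a monomorphic SNP (p = 0 or 1) cannot explain q > 0 variance",
         call. = FALSE)
  sqrt(residual_variance * q / (1 - q) / (2 * p * (1 - p)))
}

#' Variance components implied by heritability and intraclass correlation
#'
#' On the normalized scale where the polygenic, subject-level and residual
#' components sum to one, solves for (sigma_g2, sigma_c2, sigma_e2) given
#' the fraction of variance explained by the causal SNP (`q`), the narrow
#' heritability `h2` (SNP plus polygenic share of the total variance
#' including the SNP), and the subject-level share `rho` (which equals the
#' between-visit correlation when the polygenic component is absent).
#'
#' With s = q/(1-q) the SNP variance on this scale, the heritability
#' identity h2 = (s + sigma_g2)/(s + 1) gives sigma_g2 = (h2 - q)/(1 - q);
#' sigma_c2 = rho, and sigma_e2 takes the remainder.
#'
#' @param q Variance explained by the SNP, in \[0, 1).
#' @param h2 Heritability, in \[0, 1); must be at least `q`.
#' @param rho Subject-level (random-intercept) share of the phenotypic
#'   variance, in \[0, 1\].
#' @param total Total of the three components (default 1, the normalized
#'   scale); all components scale linearly in `total`.
#' @return Named numeric vector `c(sigma_g2, sigma_c2, sigma_e2)`.
#' @examples
#' variance_components(q = 0.005, h2 = 0.3, rho = 0.4)
#' @export
variance_components <- function(q, h2, rho, total = 1) {
  if (!is.finite(q) || q < 0 || q >= 1)
    stop("variance explained q must lie in [0, 1)", call. = FALSE)
  if (!is.finite(h2) || h2 < 0 || h2 >= 1)
    stop("heritability h2 must lie in [0, 1)", call. = FALSE)
  if (h2 < q)
    stop("infeasible design: heritability h2 (", h2,
         ") is below the SNP variance share q (", q, ")", call. = FALSE)
  if (!is.finite(rho) || rho < 0 || rho > 1)
    stop("rho must lie in [0, 1]", call. = FALSE)
  if (!is.finite(total) || total <= 0)
    stop("total variance must be positive", call. = FALSE)
  sigma_g2 <- (h2 - q) / (1 - q)
  if (rho > 1 - sigma_g2 + 1e-12)
    stop("infeasible design: rho (", rho, ") exceeds 1 - sigma_g2 (",
         format(1 - sigma_g2), ")", call. = FALSE)
  sigma_c2 <- rho
  sigma_e2 <- max(1 - sigma_g2 - sigma_c2, 0)
  c(sigma_g2 = sigma_g2, sigma_c2 = sigma_c2, sigma_e2 = sigma_e2) * total
}
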