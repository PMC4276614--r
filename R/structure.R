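# Population-structure adjustment: identity-by-state similarity,
# EIGENSTRAT-style principal components, and genomic control.

#' Identity-by-state similarity matrix
#'
#' Average allele sharing between every pair of subjects:
#' `IBS(i, j) = sum_k (2 - |x_ik - x_jk|) / (2 m_ij)` over the `m_ij` loci
#' observed in both subjects, so identical genotype vectors score 1 and
#' opposite homozygotes score 0.
#'
#' @param genotypes n x m dosage matrix (0/1/2, `NA` for missing); rows are
#'   subjects.
#' @return Symmetric n x n matrix with unit diagonal and entries in
#'   \[0, 1\]; a pair sharing no observed loci yields `NA` (with a warning).
#' @examples
#' ibs_matrix(rbind(c(0, 1, 2), c(2, 1, 0)))  # off-diagonal 1/3
#' @export
ibs_matrix <- function(genotypes) {
  G <- as.matrix(genotypes)
  if (ncol(G) < 1) stop("at least one locus is required", call. = FALSE)
  obs <- !is.na(G)
  A0 <- (G == 0) & obs; A1 <- (G == 1) & obs; A2 <- (G == 2) & obs
  mode(A0) <- "numeric"; mode(A1) <- "numeric"; mode(A2) <- "numeric"
  # sum over shared loci of |x_i - x_j|: distance 1 between a het and
  # either homozygote, 2 between opposite homozygotes
  d01 <- tcrossprod(A0, A1); d12 <- tcrossprod(A1, A2)
  dist_sum <- d01 + t(d01) + d12 + t(d12) +
    2 * (tcrossprod(A0, A2) + tcrossprod(A2, A0))
  m_shared <- tcrossprod(obs * 1)
  ibs <- (2 * m_shared - dist_sum) / (2 * m_shared)
  if (any(m_shared == 0)) {
    warning(sum(m_shared == 0 & upper.tri(m_shared)),
            " subject pair(s) share no observed loci; IBS set to NA")
    ibs[m_shared == 0] <- NA_real_
  }
  diag(ibs) <- 1
  rownames(ibs) <- colnames(ibs) <- rownames(G)
  ibs
}

#' Principal components of a similarity matrix
#'
#' Eigendecomposition of the double-centered similarity matrix (the
#' classical multidimensional-scaling construction). The top-k
#' eigenvectors, scaled by the square root of their eigenvalues, are
#' returned as subject scores for use as regression covariates; the
#' variance fraction is the share of the positive eigenvalue mass captured
#' by the top k.
#'
#' @param similarity Symmetric n x n similarity matrix, e.g. from
#'   [ibs_matrix()].
#' @param k Number of components (default 5).
#' @return An object of class `pca_result`: `scores` (n x k),
#'   `eigenvalues` (all n, non-increasing), `variance_fraction`.
#' @export
pca_scores <- function(similarity, k = 5) {
  S <- as.matrix(similarity)
  n <- nrow(S)
  if (n != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("similarity must be a symmetric square matrix", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of subjects", call. = FALSE)
  J <- diag(n) - matrix(1 / n, n, n)
  C <- J %*% S %*% J
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(pos[seq_len(k)]), each = n)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(S)
  structure(list(scores = scores, eigenvalues = e$values,
                 variance_fraction = sum(pos[seq_len(k)]) / sum(pos)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("PCA of similarity matrix: top %d components capture %.1f%% of the variation\n",
              k, 100 * x$variance_fraction))
  invisible(x)
}

# Median of the chi-squared distribution with 1 df, the genomic-control
# reference constant.
CHISQ1_MEDIAN <- 0.45494

#' Genomic-control inflation factor
#'
#' Estimates the inflation factor lambda as the median association
#' chi-squared statistic divided by 0.45494 (the median of a 1-df
#' chi-squared variable). Values above 1 indicate residual stratification
#' or model misfit; lambda is reported unclipped. Optionally rescales the
#' statistics by lambda and returns adjusted p-values.
#'
#' @param p Two-sided p-values from 1-df Wald tests (supply either `p` or
#'   `chisq`).
#' @param chisq 1-df chi-squared statistics.
#' @param adjust If `TRUE`, return p-values recomputed from `chisq /
#'   lambda`.
#' @return An object of class `gc_report`: `lambda`, `n_tests`, and
#'   `adjusted_p` when requested.
#' @examples
#' genomic_control(chisq = rep(0.90988, 5))$lambda  # 2
#' @export
genomic_control <- function(p = NULL, chisq = NULL, adjust = FALSE) {
  if (is.null(chisq)) {
    if (is.null(p)) stop("supply p-values or chi-squared statistics",
                         call. = FALSE)
    chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) == 0)
    stop("no finite statistics to estimate lambda from", call. = FALSE)
  lambda <- median(chisq) / CHISQ1_MEDIAN
  adjusted_p <- NULL
  if (adjust) adjusted_p <- pchisq(chisq / lambda, df = 1, lower.tail = FALSE)
  structure(list(lambda = lambda, n_tests = length(chisq),
                 adjusted_p = adjusted_p),
            class = "gc_report")
}

#' @export
print.gc_report <- function(x, ...) {
  cat(sprintf("Genomic control: lambda = %.4f over %d tests\n",
              x$lambda, x$n_tests))
  invisible(x)
}
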