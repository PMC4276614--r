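#' Longitudinal phenotype dataset
#'
#' Container for repeated phenotype measurements: one row per subject, one
#' column per visit, with an availability mask for missing visits,
#' subject-level covariates, optional genotype dosages and visit time
#' offsets.
#'
#' @param ids Character or integer subject identifiers (length n).
#' @param Y Numeric n x t phenotype matrix; entries at unobserved visits
#'   may be `NA`.
#' @param mask Logical n x t availability matrix. Defaults to `!is.na(Y)`.
#'   Every subject must be observed at the baseline visit (column 1).
#' @param Z Numeric n x p subject-level covariate matrix (should include an
#'   intercept column). Defaults to an intercept-only matrix.
#' @param snp Optional numeric dosage vector (0/1/2 copies of the minor
#'   allele) of length n.
#' @param time_offsets Visit times relative to baseline (length t);
#'   default `2 * (0:(t-1))` years, matching biennial follow-up.
#' @return An object of class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(ids, Y, mask = NULL, Z = NULL, snp = NULL,
                                 time_offsets = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  if (length(ids) != n) stop("length(ids) must equal nrow(Y)", call. = FALSE)
  if (is.null(mask)) mask <- !is.na(Y)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(Y)))
    stop("mask must have the same dimensions as Y", call. = FALSE)
  if (any(!mask[, 1]))
    stop(sum(!mask[, 1]), " subject(s) missing the baseline visit; ",
         "drop them before constructing the dataset", call. = FALSE)
  if (is.null(Z)) Z <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  Z <- as.matrix(Z)
  if (nrow(Z) != n) stop("nrow(Z) must equal nrow(Y)", call. = FALSE)
  if (is.null(colnames(Z)))
    colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  if (!is.null(snp) && length(snp) != n)
    stop("length(snp) must equal nrow(Y)", call. = FALSE)
  if (is.null(time_offsets)) time_offsets <- 2 * (seq_len(t) - 1)
  if (length(time_offsets) != t)
    stop("time_offsets must have one entry per visit", call. = FALSE)
  Y[!mask] <- NA_real_
  structure(list(ids = ids, Y = Y, mask = mask, Z = Z, snp = snp,
                 time_offsets = as.numeric(time_offsets)),
            class = "longitudinal_dataset")
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  cat(sprintf("Longitudinal dataset: %d subjects, %d visits, %d observations\n",
              nrow(x$Y), ncol(x$Y), sum(x$mask)))
  cat(sprintf("  visit time offsets: %s\n",
              paste(x$time_offsets, collapse = ", ")))
  cat(sprintf("  covariates: %s\n", paste(colnames(x$Z), collapse = ", ")))
  if (!is.null(x$snp)) cat("  SNP dosages attached\n")
  invisible(x)
}

#' Number of subjects observed at each visit
#'
#' @param data A [longitudinal_dataset()].
#' @return Integer vector of per-visit counts.
#' @export
visit_counts <- function(data) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  colSums(data$mask)
}
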