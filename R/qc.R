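# Genotype quality control: the standard pre-association filters on
# samples and SNPs, applied in a fixed, reported order.

#' Quality-control thresholds
#'
#' Defaults mirror common GWAS practice for array data: 95% call rates,
#' Hardy-Weinberg p >= 1e-6, minor-allele frequency >= 1%, per-sample
#' heterozygosity at most 30%, and pairwise identity-by-state at most 0.8
#' (flagging duplicates and close relatives).
#'
#' @param snp_call_rate Minimum fraction of non-missing genotypes per SNP.
#' @param sample_call_rate Minimum fraction of non-missing genotypes per
#'   sample.
#' @param hwe_p Minimum Hardy-Weinberg equilibrium test p-value per SNP.
#' @param maf Minimum minor-allele frequency.
#' @param heterozygosity_max Maximum fraction of heterozygous calls among a
#'   sample's non-missing genotypes.
#' @param ibs_max Maximum pairwise identity-by-state similarity.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate = 0.95, sample_call_rate = 0.95,
                          hwe_p = 1e-6, maf = 0.01,
                          heterozygosity_max = 0.30, ibs_max = 0.80) {
  vals <- c(snp_call_rate, sample_call_rate, hwe_p, maf,
            heterozygosity_max, ibs_max)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all thresholds must lie in [0, 1]", call. = FALSE)
  structure(list(snp_call_rate = snp_call_rate,
                 sample_call_rate = sample_call_rate, hwe_p = hwe_p,
                 maf = maf, heterozygosity_max = heterozygosity_max,
                 ibs_max = ibs_max),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom chi-squared goodness-of-fit test of the observed
#' genotype counts against the Hardy-Weinberg expectation at the observed
#' allele frequency. Monomorphic sites return p = 1.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of genotype counts
#'   (0, 1, 2 copies of the coded allele).
#' @return The p-value.
#' @examples
#' hwe_test(c(25, 50, 25))  # perfect HWE, p = 1
#' hwe_test(c(50, 0, 50))   # complete heterozygote deficit
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3 || any(counts < 0))
    stop("counts must be three non-negative genotype counts", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("no genotypes observed", call. = FALSE)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((counts - expected)^2 / expected)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Quality-control filter for a genotype matrix
#'
#' Applies, in order: sample call rate, SNP call rate, Hardy-Weinberg
#' equilibrium, minor-allele frequency, per-sample heterozygosity, and
#' pairwise identity-by-state. For each IBS pair above the threshold the
#' member with the lower call rate is removed (ties broken by file order:
#' the later sample goes). The per-step removal counts are reported.
#'
#' @param dosage Subjects x SNPs dosage matrix (0/1/2/NA).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `dosage` (the filtered matrix), `samples_kept`,
#'   `snps_kept` (logical vectors over the input), and `report` (data
#'   frame of per-step removal counts).
#' @export
qc_filter <- function(dosage, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  G <- as.matrix(dosage)
  n <- nrow(G); m <- ncol(G)
  sample_keep <- rep(TRUE, n); snp_keep <- rep(TRUE, m)
  steps <- character(0); removed <- integer(0)
  note <- function(step, k) {
    steps <<- c(steps, step); removed <<- c(removed, k)
  }

  cr_sample <- rowMeans(!is.na(G))
  drop <- sample_keep & cr_sample < thresholds$sample_call_rate
  sample_keep[drop] <- FALSE
  note("sample_call_rate", sum(drop))
  if (!any(sample_keep)) stop("all samples removed by QC", call. = FALSE)

  sub <- G[sample_keep, , drop = FALSE]
  cr_snp <- colMeans(!is.na(sub))
  drop <- snp_keep & cr_snp < thresholds$snp_call_rate
  snp_keep[drop] <- FALSE
  note("snp_call_rate", sum(drop))

  hwe_p <- vapply(seq_len(m), function(j) {
    if (!snp_keep[j]) return(1)
    g <- sub[, j]
    hwe_test(c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
               sum(g == 2, na.rm = TRUE)))
  }, numeric(1))
  drop <- snp_keep & hwe_p < thresholds$hwe_p
  snp_keep[drop] <- FALSE
  note("hwe", sum(drop))

  freq <- colMeans(sub, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  drop <- snp_keep & (is.na(maf) | maf < thresholds$maf)
  snp_keep[drop] <- FALSE
  note("maf", sum(drop))

  sub <- G[sample_keep, snp_keep, drop = FALSE]
  het <- rowSums(sub == 1, na.rm = TRUE) / pmax(rowSums(!is.na(sub)), 1)
  drop_idx <- which(sample_keep)[het > thresholds$heterozygosity_max]
  sample_keep[drop_idx] <- FALSE
  note("heterozygosity", length(drop_idx))
  if (!any(sample_keep)) stop("all samples removed by QC", call. = FALSE)

  ibs_removed <- 0L
  keep_idx <- which(sample_keep)
  if (length(keep_idx) >= 2 && sum(snp_keep) >= 1) {
    sub <- G[keep_idx, snp_keep, drop = FALSE]
    ibs <- ibs_matrix(sub)
    cr <- rowMeans(!is.na(sub))
    repeat {
      ibs_local <- ibs
      diag(ibs_local) <- 0
      flagged <- which(!is.na(ibs_local) & ibs_local > thresholds$ibs_max,
                       arr.ind = TRUE)
      if (nrow(flagged) == 0) break
      pair <- flagged[1, ]
      i <- pair[1]; j <- pair[2]
      victim <- if (cr[i] < cr[j]) i else if (cr[j] < cr[i]) j else max(i, j)
      sample_keep[keep_idx[victim]] <- FALSE
      ibs_removed <- ibs_removed + 1L
      ibs[victim, ] <- NA; ibs[, victim] <- NA
    }
  }
  note("ibs", ibs_removed)
  if (!any(sample_keep)) stop("all samples removed by QC", call. = FALSE)

  list(dosage = G[sample_keep, snp_keep, drop = FALSE],
       samples_kept = sample_keep, snps_kept = snp_keep,
       report = data.frame(step = steps, removed = removed,
                           stringsAsFactors = FALSE))
}
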