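# Readers and writers for the delimited formats the toolkit exchanges:
# additive-dosage tables, long-format phenotype tables, PC-score tables and
# VCF genotypes (via the vcfR package). All delimited files are
# tab-separated UTF-8 with a header row.

#' Read a genotype matrix
#'
#' Reads genotypes either from a VCF (diploid GT field, biallelic sites)
#' or from an additive-dosage table (first column `id`, one column per
#' SNP, values 0/1/2/NA). Dosages are oriented to count the minor allele:
#' VCF sites where the ALT allele is the major allele are flipped (and the
#' flip recorded). Multi-allelic VCF sites are skipped with a message.
#'
#' @param path Path to the file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A list with `dosage` (subjects x SNPs numeric matrix, subject
#'   ids as rownames) and `info` (data frame: `snp`, `chrom`, `pos`,
#'   `minor_allele`, `flipped`).
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "dosage_tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (names(tab)[1] != "id")
      stop("dosage table must start with an 'id' column", call. = FALSE)
    dosage <- as.matrix(tab[, -1, drop = FALSE])
    mode(dosage) <- "numeric"
    rownames(dosage) <- as.character(tab$id)
    info <- data.frame(snp = colnames(dosage), chrom = NA_character_,
                       pos = NA_integer_, minor_allele = NA_character_,
                       flipped = FALSE, stringsAsFactors = FALSE)
    return(list(dosage = dosage, info = info))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multi-allelic site(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  # ALT-allele dosage from diploid GT, either separator
  alt_dose <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(al) {
      if (length(al) != 2 || any(al == ".") || any(is.na(al)))
        return(NA_real_)
      sum(al == "1")
    }, numeric(1))
  }
  dosage <- t(apply(gt, 1, alt_dose))
  dosage <- matrix(dosage, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  dosage <- t(dosage)              # subjects x SNPs
  alt_freq <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  dosage[, flip] <- 2 - dosage[, flip]
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  colnames(dosage) <- ids
  info <- data.frame(
    snp = ids, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    minor_allele = ifelse(flip, fix[, "REF"], fix[, "ALT"]),
    flipped = flip, stringsAsFactors = FALSE, row.names = NULL)
  list(dosage = dosage, info = info)
}

#' Write an additive-dosage table
#'
#' @param dosage Subjects x SNPs numeric matrix with subject ids as
#'   rownames.
#' @param path Output path (tab-separated, header `id` + SNP names).
#' @return The path, invisibly.
#' @export
write_dosage <- function(dosage, path) {
  ids <- rownames(dosage)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(dosage)))
  tab <- data.frame(id = ids, dosage, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Expects one row per (subject, visit) with columns `id`, `visit`
#' (1-based index), `time_offset` (years from baseline), `value`
#' (the phenotype), and any subject-level covariate columns (e.g. `sex`,
#' `age`, `weight`; covariates are taken from the baseline row).
#'
#' @param path Path to the tab-separated table.
#' @return A [longitudinal_dataset()]; covariate columns are carried in
#'   `$Z` (after an intercept) and the raw baseline covariate table in
#'   `$covariate_table`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "visit", "time_offset", "value")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0)
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab[, c("id", "visit")]) > 0)
    stop("duplicate (id, visit) row(s) in phenotype table", call. = FALSE)
  visits <- sort(unique(tab$visit))
  offsets <- vapply(visits, function(v)
    unique(tab$time_offset[tab$visit == v])[1], numeric(1))
  for (v in seq_along(visits)) {
    off_v <- unique(tab$time_offset[tab$visit == visits[v]])
    if (length(off_v) != 1)
      stop("visit ", visits[v], " has inconsistent time offsets",
           call. = FALSE)
  }
  if (is.unsorted(offsets, strictly = TRUE))
    stop("visit time offsets must be strictly increasing", call. = FALSE)
  ids <- unique(tab$id)
  n <- length(ids); t <- length(visits)
  Y <- matrix(NA_real_, n, t)
  row_ix <- match(tab$id, ids)
  col_ix <- match(tab$visit, visits)
  Y[cbind(row_ix, col_ix)] <- tab$value
  covariate_cols <- setdiff(names(tab), required)
  base <- tab[tab$visit == visits[1], , drop = FALSE]
  base <- base[match(ids, base$id), , drop = FALSE]
  Z <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  covariate_table <- NULL
  if (length(covariate_cols) > 0) {
    covariate_table <- base[, covariate_cols, drop = FALSE]
    rownames(covariate_table) <- NULL
    numeric_cov <- covariate_cols[vapply(covariate_table, is.numeric,
                                         logical(1))]
    if (length(numeric_cov) > 0)
      Z <- cbind(Z, as.matrix(covariate_table[, numeric_cov, drop = FALSE]))
  }
  out <- longitudinal_dataset(ids = ids, Y = Y, Z = Z,
                              time_offsets = offsets)
  out$covariate_table <- covariate_table
  out
}

#' Write a longitudinal dataset as a long-format phenotype table
#'
#' Inverse of [read_phenotypes()]: one row per observed (subject, visit).
#'
#' @param data A [longitudinal_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(data, path) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  n <- nrow(data$Y); t <- ncol(data$Y)
  rows <- which(data$mask, arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  tab <- data.frame(id = data$ids[rows[, 1]], visit = rows[, 2],
                    time_offset = data$time_offsets[rows[, 2]],
                    value = data$Y[rows], stringsAsFactors = FALSE)
  keep_cov <- setdiff(colnames(data$Z), "intercept")
  for (col in keep_cov) tab[[col]] <- data$Z[rows[, 1], col]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write principal-component scores
#'
#' @param pca A `pca_result` from [pca_scores()].
#' @param ids Subject identifiers.
#' @param path Output path (tab-separated: `id`, `PC1`..`PCk`).
#' @return The path, invisibly.
#' @export
write_pc_scores <- function(pca, ids, path) {
  tab <- data.frame(id = ids, pca$scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
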