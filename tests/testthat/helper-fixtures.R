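# Fixtures built in code: random trinomials, a two-population genotype
# panel, a QC fixture tripping each filter once, and a dense-matrix GLS
# oracle independent of the package's pattern-grouped solver.

# Random trinomial probability vectors (rows sum to 1).
random_trinomials <- function(n) {
  u <- matrix(stats::rexp(3 * n), n, 3)
  u / rowSums(u)
}

# Variance of the coded genotype computed by brute force over the three
# outcomes 0, 1, 2.
var_coded_genotype <- function(pi) {
  x <- c(0, 1, 2)
  sum(pi * x^2) - sum(pi * x)^2
}

# Dense stacked GLS solve: block-diagonal weight matrix, explicit design.
# U holds subject-level columns, V time-slope multipliers, Sigma is known.
dense_gls_oracle <- function(Y, mask, U, V, w, Sigma) {
  n <- nrow(Y); t <- ncol(Y)
  X <- NULL; yv <- NULL; Wblocks <- list()
  for (i in seq_len(n)) {
    o <- which(mask[i, ])
    Di <- cbind(matrix(rep(U[i, ], each = length(o)), nrow = length(o)),
                if (!is.null(V))
                  matrix(rep(V[i, ], each = length(o)) * w[o],
                         nrow = length(o)))
    X <- rbind(X, Di)
    yv <- c(yv, Y[i, o])
    Wblocks[[i]] <- solve(Sigma[o, o, drop = FALSE])
  }
  W <- matrix(0, length(yv), length(yv))
  pos <- 1
  for (i in seq_len(n)) {
    k <- nrow(Wblocks[[i]])
    W[pos:(pos + k - 1), pos:(pos + k - 1)] <- Wblocks[[i]]
    pos <- pos + k
  }
  A <- t(X) %*% W %*% X
  list(coef = drop(solve(A, t(X) %*% W %*% yv)), vcov = solve(A))
}

# Two populations with divergent allele frequencies; returns the dosage
# matrix and the population label.
two_population_panel <- function(n_per_pop = 60, m = 200, delta = 0.3) {
  f1 <- stats::runif(m, 0.1, 0.5)
  f2 <- pmin(f1 + delta, 0.9)
  g1 <- sapply(f1, function(f) stats::rbinom(n_per_pop, 2, f))
  g2 <- sapply(f2, function(f) stats::rbinom(n_per_pop, 2, f))
  list(dosage = rbind(g1, g2),
       pop = rep(c(0, 1), each = n_per_pop))
}

# Genotype matrix built to trip each QC rule exactly once: sample S1 has
# a 50% call rate, snp2 has a 60% call rate once S1 is gone, snp1 is
# monomorphic (MAF 0 < 0.01). The benign block (snp3..snp22) assigns each
# kept sample four private homozygous-alternate columns, so heterozygosity
# stays at 0, per-SNP MAF is 0.2, the all-homozygote HWE chi-squared is 5
# (p ~ 0.025, above 1e-6), every pairwise IBS is 0.6, and a single missing
# call still leaves S2/S3 at 21/22 = 0.955 sample call rate.
qc_fixture <- function() {
  benign <- matrix(0, 5, 20)
  for (k in 1:5) benign[k, (4 * k - 3):(4 * k)] <- 2
  G <- cbind(rep(0, 6),                      # snp1: monomorphic
             c(NA, NA, NA, 0, 2, 0),         # snp2: 60% called sans S1
             rbind(rep(0, 20), benign))
  G[1, 2:12] <- NA                           # S1: half the genome missing
  dimnames(G) <- list(paste0("S", 1:6), paste0("snp", 1:22))
  G
}
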