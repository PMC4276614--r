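# Generalized least squares for repeated phenotype measurements with an
# unstructured t x t within-subject covariance.
#
# The model for subject i with visit times w is
#   Y_i = (U_i') 1_t + (V_i') w + e_i,   e_i ~ MVN(0, Sigma),
# where every design column is either "subject-level" (a per-subject value
# multiplying the all-ones vector: intercept, sex, age, SNP dosage, PC
# scores, sex-by-SNP products) or "time-slope" (a per-subject multiplier on
# the visit-time vector: the aging effect, multiplier 1; a time-by-SNP
# interaction, multiplier equal to the dosage). This structure lets the
# normal equations be accumulated with dense cross-products over subjects
# grouped by missingness pattern instead of a per-subject loop, so cohort
# sized fits cost a few matrix products.

# Core fitting routine. Y is n x t with unobserved cells ignored via mask;
# U (n x p1) holds subject-level columns, V (n x p2, possibly 0 columns)
# holds time-slope multipliers. If sigma is supplied it is treated as known
# (single GLS pass); otherwise the covariance is estimated by iterated
# feasible GLS: OLS start, method-of-moments update from pairwise-complete
# residual cross-products, iterate to convergence.
fit_gls_core <- function(Y, mask, U, V, w, sigma = NULL,
                         tol = 1e-8, max_iter = 50L) {
  n <- nrow(Y); t <- ncol(Y)
  p1 <- ncol(U); p2 <- if (is.null(V)) 0L else ncol(V)
  if (p2 == 0L) V <- matrix(0, n, 0)
  Y0 <- Y
  Y0[!mask] <- 0

  pattern_key <- as.vector(mask %*% 2^(seq_len(t) - 1))
  groups <- split(seq_len(n), pattern_key)
  pat_obs <- lapply(groups, function(ix) which(mask[ix[1], ]))

  solve_pass <- function(S) {
    A <- matrix(0, p1 + p2, p1 + p2)
    bvec <- numeric(p1 + p2)
    for (g in seq_along(groups)) {
      ix <- groups[[g]]; o <- pat_obs[[g]]
      Wo <- chol2inv(chol(S[o, o, drop = FALSE]))
      ones <- rep(1, length(o)); wo <- w[o]
      Wo1 <- Wo %*% ones; Wow <- Wo %*% wo
      a <- sum(Wo1); b <- sum(wo * Wo1); cc <- sum(wo * Wow)
      Us <- U[ix, , drop = FALSE]
      Ys <- Y0[ix, o, drop = FALSE]
      y1 <- Ys %*% Wo1
      A[1:p1, 1:p1] <- A[1:p1, 1:p1] + crossprod(Us) * a
      bvec[1:p1] <- bvec[1:p1] + crossprod(Us, y1)
      if (p2 > 0) {
        Vs <- V[ix, , drop = FALSE]
        yw <- Ys %*% Wow
        A[1:p1, p1 + 1:p2] <- A[1:p1, p1 + 1:p2] + crossprod(Us, Vs) * b
        A[p1 + 1:p2, p1 + 1:p2] <- A[p1 + 1:p2, p1 + 1:p2] +
          crossprod(Vs) * cc
        bvec[p1 + 1:p2] <- bvec[p1 + 1:p2] + crossprod(Vs, yw)
      }
    }
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) {
      d <- sqrt(diag(A))
      qrA <- qr(A / outer(d, d))
      bad <- colnames(U_V_names)[qrA$pivot[seq.int(qrA$rank + 1, nrow(A))]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    vcov <- chol2inv(R)
    list(coef = drop(vcov %*% bvec), vcov = vcov)
  }

  U_V_names <- c(colnames(U), colnames(V))

  update_sigma <- function(coef) {
    fit <- tcrossprod(U %*% coef[1:p1], rep(1, t))
    if (p2 > 0) fit <- fit + tcrossprod(V %*% coef[p1 + 1:p2], w)
    R <- (Y0 - fit) * mask
    npair <- crossprod(mask * 1)
    S <- crossprod(R) / pmax(npair, 1)
    S[npair == 0] <- 0
    S
  }

  ridge_delta <- 0
  repair_pd <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10 * max(abs(ev), 1)) {
      delta <- abs(min(ev)) + 1e-8 * max(abs(ev), 1)
      ridge_delta <<- delta
      warning("estimated within-subject covariance not positive definite; ",
              "ridge ", format(delta), " added to the diagonal")
      S <- S + diag(delta, nrow(S))
    }
    S
  }

  if (!is.null(sigma)) {
    sigma <- as.matrix(sigma)
    fit <- solve_pass(sigma)
    return(list(coef = fit$coef, vcov = fit$vcov, sigma = sigma,
                iterations = 0L, converged = TRUE, ridge_delta = 0,
                terms = U_V_names))
  }

  S <- diag(1, t)                     # identity start: stacked OLS
  fit <- solve_pass(S)
  S <- repair_pd(update_sigma(fit$coef))
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    fit <- solve_pass(S)
    S_new <- repair_pd(update_sigma(fit$coef))
    delta <- max(abs(S_new - S))
    S <- S_new
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  fit <- solve_pass(S)
  list(coef = fit$coef, vcov = fit$vcov, sigma = S, iterations = iterations,
       converged = converged, ridge_delta = ridge_delta, terms = U_V_names)
}

# Assemble a gls_fit object from the core output.
make_gls_fit <- function(core, n_subjects, n_obs, model) {
  se <- sqrt(diag(core$vcov))
  z <- core$coef / se
  coefficients <- data.frame(
    term = core$terms, estimate = core$coef, se = se, z = z,
    p = 2 * pnorm(-abs(z)), row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefficients, sigma = core$sigma,
                 iterations = core$iterations, converged = core$converged,
                 ridge_delta = core$ridge_delta, n_subjects = n_subjects,
                 n_obs = n_obs, model = model),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d subjects, %d observations\n",
              x$model, x$n_subjects, x$n_obs))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  if (x$iterations > 0)
    cat(sprintf("Covariance estimated in %d iteration(s)%s\n", x$iterations,
                if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Extract a coefficient row from a fit
#'
#' @param fit A `gls_fit` object.
#' @param term Coefficient name, e.g. `"SNP"`.
#' @return One-row data frame with estimate, se, z and p.
#' @export
coef_term <- function(fit, term) {
  stopifnot(inherits(fit, "gls_fit"))
  row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (nrow(row) == 0)
    stop("no coefficient named '", term, "' in the fit", call. = FALSE)
  row
}

# Validate/assemble the design pieces shared by the longitudinal and
# cross-sectional fitters. Subjects without an observed baseline visit are
# excluded up front (the constructor already enforces this, but subsetted
# data may reintroduce it).
assemble_design <- function(data, snp, covariates, pcs) {
  if (is.null(snp)) snp <- data$snp
  if (is.null(snp)) stop("no SNP dosage supplied", call. = FALSE)
  if (is.null(covariates)) covariates <- data$Z
  U <- cbind(covariates, SNP = snp)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    U <- cbind(U, pcs)
  }
  keep <- rowSums(data$mask) > 0 & !is.na(snp) & rowSums(is.na(U)) == 0
  list(U = U, snp = snp, keep = keep)
}

#' Longitudinal association fit by generalized least squares
#'
#' Fits the repeated-measures association model
#' `Y_i = Z_i alpha + (X_i beta) 1_t + PC_i gamma + w eta + e_i`,
#' with `e_i ~ MVN(0, Sigma)` and Sigma an unstructured t x t covariance
#' common to all subjects, estimated by iterated feasible generalized least
#' squares (ordinary least squares start, covariance updated from
#' pairwise-complete residual cross-products, iterated to convergence).
#' Missing visits are handled by per-subject subsetting of Sigma, valid
#' when missingness does not depend on the unobserved phenotypes. The Wald
#' test of the SNP coefficient uses the standard-normal reference.
#'
#' @param data A [longitudinal_dataset()].
#' @param snp Dosage vector (0/1/2); defaults to `data$snp`.
#' @param covariates Subject-level covariate matrix including the
#'   intercept; defaults to `data$Z`.
#' @param pcs Optional matrix of principal-component scores (see
#'   [pca_scores()]).
#' @param interaction Optional environment variable to interact with the
#'   SNP: the name of a covariate column (e.g. `"sex"`, `"age"`) or
#'   `"time"` for a visit-time by SNP slope.
#' @param sigma Optional known within-subject covariance; when supplied no
#'   iteration is performed (useful for oracles and calibration).
#' @param tol Convergence tolerance on the largest absolute change of any
#'   Sigma entry between iterations.
#' @param max_iter Iteration cap.
#' @return A `gls_fit` object: coefficient table (`term`, `estimate`, `se`,
#'   `z`, `p`), estimated `sigma`, iteration count and convergence flag.
#' @examples
#' set.seed(1)
#' d <- simulate_cohort(sim_spec(n = 500, t = 3, maf = 0.3, beta = 0.3,
#'                               sigma_c2 = 0.4, sigma_e2 = 0.6))
#' fit <- fit_gls_longitudinal(d)
#' coef_term(fit, "SNP")
#' @export
fit_gls_longitudinal <- function(data, snp = NULL, covariates = NULL,
                                 pcs = NULL, interaction = NULL, sigma = NULL,
                                 tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  t <- ncol(data$Y)
  des <- assemble_design(data, snp, covariates, pcs)
  U <- des$U; snp <- des$snp
  V <- NULL
  if (t > 1) {
    V <- matrix(1, nrow(U), 1, dimnames = list(NULL, "time"))
    if (identical(interaction, "time"))
      V <- cbind(V, `time:SNP` = snp)
  } else if (identical(interaction, "time")) {
    stop("a time-by-SNP interaction needs more than one visit", call. = FALSE)
  }
  if (!is.null(interaction) && !identical(interaction, "time")) {
    env <- U[, interaction]
    if (length(unique(env[des$keep])) < 2)
      stop("interaction variable '", interaction,
           "' is constant; interaction inestimable", call. = FALSE)
    U <- cbind(U, snp * env)
    colnames(U)[ncol(U)] <- paste0(interaction, ":SNP")
  }
  keep <- des$keep
  core <- fit_gls_core(data$Y[keep, , drop = FALSE],
                       data$mask[keep, , drop = FALSE],
                       U[keep, , drop = FALSE],
                       if (is.null(V)) NULL else V[keep, , drop = FALSE],
                       data$time_offsets, sigma = sigma,
                       tol = tol, max_iter = max_iter)
  make_gls_fit(core, sum(keep), sum(data$mask[keep, ]), "longitudinal GLS")
}

#' Cross-sectional association fit at the baseline visit
#'
#' Ordinary least squares on the baseline (first-visit) phenotypes with the
#' same covariate and principal-component adjustment as the longitudinal
#' model, minus the visit-time effect. Equivalent to the longitudinal
#' fitter applied to a single visit.
#'
#' @inheritParams fit_gls_longitudinal
#' @param interaction Optional covariate name to interact with the SNP
#'   (`"time"` is not available cross-sectionally).
#' @return A `gls_fit` object.
#' @export
fit_ols_cross_sectional <- function(data, snp = NULL, covariates = NULL,
                                    pcs = NULL, interaction = NULL) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  base <- longitudinal_dataset(
    ids = data$ids, Y = data$Y[, 1, drop = FALSE],
    mask = data$mask[, 1, drop = FALSE], Z = data$Z, snp = data$snp,
    time_offsets = data$time_offsets[1])
  fit <- fit_gls_longitudinal(base, snp = snp, covariates = covariates,
                              pcs = pcs, interaction = interaction)
  fit$model <- "cross-sectional OLS"
  fit
}

#' Gene-by-environment interaction test
#'
#' Augments the longitudinal (or cross-sectional) association model with a
#' product term between the SNP dosage and an environment variable and
#' tests the interaction coefficient by a Wald test. Main effects of both
#' the SNP and the environment are always retained.
#'
#' @inheritParams fit_gls_longitudinal
#' @param environment `"sex"`, `"age"` (any covariate column name), or
#'   `"time"` for a visit-time interaction (longitudinal model only).
#' @param model `"longitudinal"` or `"cross"`.
#' @return A `gls_fit`; the interaction row is named `"<env>:SNP"`
#'   (`"time:SNP"` for the time interaction).
#' @export
fit_interaction <- function(data, snp = NULL, environment,
                            model = c("longitudinal", "cross"),
                            covariates = NULL, pcs = NULL) {
  model <- match.arg(model)
  if (model == "cross") {
    if (identical(environment, "time"))
      stop("the time interaction requires the longitudinal model",
           call. = FALSE)
    fit_ols_cross_sectional(data, snp = snp, covariates = covariates,
                            pcs = pcs, interaction = environment)
  } else {
    fit_gls_longitudinal(data, snp = snp, covariates = covariates,
                         pcs = pcs, interaction = environment)
  }
}

#' Covariate matrix for a phenotype's association scan
#'
#' Builds the standard adjustment set: intercept, sex, baseline age and
#' age squared; fasting and post-load glucose scans (`GLU0`, `GLU120`)
#' additionally adjust for weight.
#'
#' @param covariate_table Data frame with one row per subject and columns
#'   `sex`, `age` (baseline), and `weight` when required.
#' @param phenotype Phenotype name; `"GLU0"` and `"GLU120"` trigger the
#'   weight adjustment.
#' @return Numeric covariate matrix with named columns, ready for
#'   [fit_gls_longitudinal()].
#' @export
build_covariates <- function(covariate_table, phenotype) {
  needs_weight <- phenotype %in% c("GLU0", "GLU120")
  required <- c("sex", "age", if (needs_weight) "weight")
  missing_cols <- setdiff(required, names(covariate_table))
  if (length(missing_cols) > 0)
    stop("covariate table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in required) {
    bad <- which(is.na(covariate_table[[col]]))
    if (length(bad) > 0)
      stop("missing '", col, "' for subject row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  age <- covariate_table$age
  if (stats::var(age) == 0)
    stop("age is constant: age^2 would be collinear with the intercept",
         call. = FALSE)
  Z <- cbind(intercept = 1, sex = covariate_table$sex, age = age,
             age2 = age^2)
  if (needs_weight) Z <- cbind(Z, weight = covariate_table$weight)
  Z
}

#' Genome-wide association scan
#'
#' Applies the longitudinal, cross-sectional or interaction model to every
#' SNP of a dosage matrix and returns one association record per SNP.
#' Per-SNP failures (monomorphic sites, collinearity) are recorded as `NA`
#' rows with a reason code and never abort the scan.
#'
#' @param data A [longitudinal_dataset()].
#' @param genotypes n x m dosage matrix (columns are SNPs, `NA` allowed).
#' @param snp_info Optional data frame with columns `snp`, `chrom`, `pos`,
#'   `minor_allele`, aligned with the columns of `genotypes`; results are
#'   ordered by (chrom, pos) when present.
#' @param model `"longitudinal"`, `"cross"`, or `"interaction"`.
#' @param environment Environment variable for the interaction model.
#' @param covariates,pcs Passed to the fitters.
#' @param suggestive Suggestive threshold used to flag candidates for
#'   replication (default 1e-6).
#' @param n_tests Number of tests for the Bonferroni genome-wide threshold
#'   `0.05 / n_tests`; defaults to the number of SNPs scanned.
#' @return Data frame with one row per SNP: identifiers, MAF, model tag,
#'   `beta`, `se`, `p`, subject and observation counts, `suggestive` and
#'   `genome_wide` flags, and a `note` for skipped SNPs.
#' @export
gwas_scan <- function(data, genotypes, snp_info = NULL,
                      model = c("longitudinal", "cross", "interaction"),
                      environment = NULL, covariates = NULL, pcs = NULL,
                      suggestive = 1e-6, n_tests = NULL) {
  model <- match.arg(model)
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (is.null(n_tests)) n_tests <- max(m, 1)
  gw_threshold <- bonferroni_threshold(n_tests)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(max(m, 0)))
  term <- switch(model, longitudinal = "SNP", cross = "SNP",
                 interaction = if (identical(environment, "time"))
                   "time:SNP" else paste0(environment, ":SNP"))
  tag <- switch(model, longitudinal = "longitudinal",
                cross = "cross-sectional",
                interaction = paste0("interaction:", environment))
  rows <- vector("list", m)
  for (j in seq_len(max(m, 0))) {
    g <- genotypes[, j]
    maf <- mean(g, na.rm = TRUE) / 2
    maf <- min(maf, 1 - maf)
    rec <- data.frame(snp = ids[j], chrom = NA_character_, pos = NA_integer_,
                      minor_allele = NA_character_, maf = maf, model = tag,
                      beta = NA_real_, se = NA_real_, p = NA_real_,
                      n_subjects = NA_integer_, n_obs = NA_integer_,
                      note = "", stringsAsFactors = FALSE)
    if (!is.null(snp_info)) {
      rec$chrom <- as.character(snp_info$chrom[j])
      rec$pos <- snp_info$pos[j]
      if (!is.null(snp_info$minor_allele))
        rec$minor_allele <- as.character(snp_info$minor_allele[j])
    }
    if (is.na(maf) || maf == 0) {
      rec$note <- "monomorphic"
    } else {
      fit <- tryCatch({
        f <- switch(model,
          longitudinal = fit_gls_longitudinal(data, snp = g,
            covariates = covariates, pcs = pcs),
          cross = fit_ols_cross_sectional(data, snp = g,
            covariates = covariates, pcs = pcs),
          interaction = fit_interaction(data, snp = g,
            environment = environment, covariates = covariates, pcs = pcs))
        row <- coef_term(f, term)
        rec$beta <- row$estimate; rec$se <- row$se; rec$p <- row$p
        rec$n_subjects <- f$n_subjects; rec$n_obs <- f$n_obs
        rec
      }, error = function(e) { rec$note <- conditionMessage(e); rec })
      rec <- fit
    }
    rows[[j]] <- rec
  }
  out <- if (m > 0) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else NULL
  if (is.null(out)) {
    out <- data.frame(snp = character(), chrom = character(),
                      pos = integer(), minor_allele = character(),
                      maf = numeric(), model = character(), beta = numeric(),
                      se = numeric(), p = numeric(), n_subjects = integer(),
                      n_obs = integer(), note = character(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(snp_info))
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$suggestive <- !is.na(out$p) & out$p < suggestive
  out$genome_wide <- !is.na(out$p) & out$p < gw_threshold
  rownames(out) <- NULL
  out
}

#' Bonferroni genome-wide significance threshold
#'
#' @param n_tests Number of SNPs tested.
#' @param fwer Family-wise error rate (default 0.05).
#' @return `fwer / n_tests`.
#' @examples
#' bonferroni_threshold(352228)  # 1.4e-7
#' @export
bonferroni_threshold <- function(n_tests, fwer = 0.05) {
  if (!is.finite(n_tests) || n_tests < 1)
    stop("n_tests must be >= 1", call. = FALSE)
  fwer / n_tests
}
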