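# Direction-aware replication p-values and combined evidence across
# cohorts by Fisher's and Liptak's (weighted-Z) methods.

#' One-sided replication p-value oriented to the discovery direction
#'
#' Converts a replication cohort's two-sided p-value into a one-sided
#' p-value for the alternative whose sign matches the discovery estimate:
#' `p/2` when the replication estimate has the expected sign, `1 - p/2`
#' when it points the other way (so discordant replications yield p > 0.5),
#' and exactly 0.5 for a zero estimate.
#'
#' @param beta Replication-cohort effect estimate (only its sign is used).
#' @param p_two_sided Two-sided p-value from the replication cohort.
#' @param expected_sign Sign of the discovery-cohort estimate (+1 or -1).
#' @return The one-sided p-value.
#' @examples
#' one_sided_p(-1.65, 1.27e-4, expected_sign = -1)  # concordant: 6.35e-5
#' @export
one_sided_p <- function(beta, p_two_sided, expected_sign) {
  if (any(p_two_sided <= 0 | p_two_sided > 1))
    stop("two-sided p-values must lie in (0, 1]", call. = FALSE)
  s <- sign(expected_sign)
  if (any(s == 0)) stop("expected_sign must be non-zero", call. = FALSE)
  out <- ifelse(sign(beta) == s, p_two_sided / 2, 1 - p_two_sided / 2)
  out[beta == 0] <- 0.5
  out
}

#' Combine p-values by Fisher's method
#'
#' `X2 = -2 sum(log(p_i))` referred to a chi-squared distribution with
#' `2k` degrees of freedom.
#'
#' @param p Vector of p-values in (0, 1]. Exact zeros are an error; floor
#'   them explicitly (e.g. at 1e-300) if required.
#' @return An object of class `combined_pvalues` with `method`,
#'   `statistic`, `df` and `p`.
#' @examples
#' fisher_combine(c(4.46e-9, 0.358))  # combined p = 3.39e-8
#' @export
fisher_combine <- function(p) {
  if (length(p) < 1) stop("at least one p-value is required", call. = FALSE)
  if (any(p <= 0))
    stop("p-values must be positive; floor exact zeros explicitly",
         call. = FALSE)
  if (any(p > 1)) stop("p-values cannot exceed 1", call. = FALSE)
  x2 <- -2 * sum(log(p))
  structure(list(method = "fisher", statistic = x2, df = 2 * length(p),
                 p = pchisq(x2, df = 2 * length(p), lower.tail = FALSE)),
            class = "combined_pvalues")
}

#' Combine p-values by Liptak's weighted-Z method
#'
#' Transforms each p-value to a normal quantile `z_i = qnorm(1 - p_i)`,
#' combines them as `z = sum(w_i z_i) / sqrt(sum(w_i^2))`, and reports
#' `p = 1 - pnorm(z)`. The default weights are the square roots of the
#' cohort sample sizes, the choice under which Liptak's method is most
#' efficient when effect sizes are expected to be equal across cohorts.
#'
#' @param p Vector of p-values, strictly inside (0, 1).
#' @param n Cohort sample sizes (weights are `sqrt(n)`); alternatively
#'   supply `weights` directly.
#' @param weights Optional explicit weights, overriding `n`.
#' @return An object of class `combined_pvalues` with `method`, `z`, `p`
#'   and the `weights` used.
#' @examples
#' liptak_combine(c(4.46e-9, 0.358), n = c(8841, 3703))  # p = 2.52e-7
#' @export
liptak_combine <- function(p, n = NULL, weights = NULL) {
  if (length(p) < 1) stop("at least one p-value is required", call. = FALSE)
  if (any(p <= 0 | p >= 1))
    stop("p-values must lie strictly in (0, 1) for the normal quantile",
         call. = FALSE)
  if (is.null(weights)) {
    if (is.null(n))
      stop("supply cohort sizes n (weights sqrt(n)) or explicit weights",
           call. = FALSE)
    if (any(n <= 0)) stop("cohort sizes must be positive", call. = FALSE)
    weights <- sqrt(n)
  }
  if (length(weights) != length(p))
    stop("one weight per p-value is required", call. = FALSE)
  z <- sum(weights * qnorm(1 - p)) / sqrt(sum(weights^2))
  structure(list(method = "liptak", z = z, p = pnorm(z, lower.tail = FALSE),
                 weights = weights),
            class = "combined_pvalues")
}

#' @export
print.combined_pvalues <- function(x, ...) {
  if (x$method == "fisher") {
    cat(sprintf("Fisher combination: X2 = %.4g on %d df, p = %.3g\n",
                x$statistic, x$df, x$p))
  } else {
    cat(sprintf("Liptak combination: z = %.4g, p = %.3g (weights %s)\n",
                x$z, x$p, paste(signif(x$weights, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Combine discovery and replication evidence across cohorts
#'
#' Convenience wrapper producing both the Fisher and Liptak combinations
#' for one SNP. The inputs are the p-values as reported per cohort
#' (typically a two-sided discovery p-value and a direction-oriented
#' one-sided replication p-value from [one_sided_p()]).
#'
#' @param p Per-cohort p-values.
#' @param n Per-cohort sample sizes for the Liptak weights.
#' @return A list with elements `fisher` and `liptak`.
#' @export
combine_cohorts <- function(p, n) {
  list(fisher = fisher_combine(p), liptak = liptak_combine(p, n = n))
}
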