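---
title: "Design and analysis of repeated-measures GWAS with repgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and analysis of repeated-measures GWAS with repgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repgwas)
```

This vignette documents the statistical model behind `repgwas`, the
derivation of its design formulas, the association engine, the simulator's
generative assumptions and limits, and the conventions adopted where more
than one defensible choice existed.

## 1. The phenotype model

For subject $i = 1, \dots, n$ at visit $j = 1, \dots, t$ with time offset
$w_j$ from baseline ($w_1 = 0$):

$$
y_{ij} = \boldsymbol\alpha' \mathbf z_i + \eta\, w_j + \beta g_i
         + c_i + e_{ij},
$$

where $\mathbf z_i$ are subject-level covariates (intercept, sex, age,
age$^2$, …), $g_i \in \{0, 1, 2\}$ is the coded genotype,
$c_i \sim N(0, \sigma_c^2)$ is a subject random intercept, and
$e_{ij} \sim N(0, \sigma_e^2)$ is visit noise. The implied within-subject
covariance is compound-symmetric, with between-visit correlation
$\rho = \sigma_c^2 / (\sigma_c^2 + \sigma_e^2)$ on the scale of the non-SNP
residual. The analysis engine does **not** assume this structure: it
estimates an unstructured $t \times t$ covariance.

### Genotype variance

For an arbitrary genotype distribution $(\pi_1, \pi_2, \pi_3)$ over
dosages $(0, 1, 2)$, the variance of the coded genotype is

$$
K = \pi_1(\pi_2 + 2\pi_3)^2 + \pi_2(\pi_3 - \pi_1)^2
  + \pi_3(1 + \pi_1 - \pi_3)^2,
$$

which `k_statistic()` evaluates and the test suite verifies against the
brute-force variance over the three outcomes. Under Hardy–Weinberg
equilibrium with minor-allele frequency $p$, $K = 2p(1-p)$.

## 2. Sample size and power

The GLS estimator of $\beta$ with known compound-symmetric covariance has
variance $\sigma_p^2 (1 + (t-1)\rho) / (n K t)$, giving the required sample
size for two-sided level $\alpha$ and power $\varphi$:

$$
n = \frac{(z_{1-\alpha/2} + z_{\varphi})^2\, \sigma_p^2}{K\beta^2}
    \cdot \frac{1 + (t-1)\rho}{t}.
$$

Two conventions matter here and are fixed throughout the package:

* **$\sigma_p^2$ excludes the SNP variance.** $\sigma_p^2 = \sigma_g^2 +
  \sigma_c^2 + \sigma_e^2$ is the phenotypic variance *net of the tested
  variant*. With small per-SNP effects the distinction is numerically
  minor, but keeping it exact makes the variance-explained
  parameterisation below internally consistent, and the Monte-Carlo and
  analytic calculators agree only under this convention.
* **Variance-explained parameterisation.** If the variant explains a
  fraction $q$ of total phenotypic variance, then
  $K\beta^2 = \sigma_p^2\, q/(1-q)$, and the allele frequency cancels out
  of $n$ entirely. `design_spec(q = ...)` uses this MAF-free form;
  `effect_size_from_q()` recovers the per-allele $\beta$ at a given MAF
  when a simulator needs one. The test suite checks that $n$ is invariant
  to MAF under this parameterisation to $10^{-12}$ relative error.

Rounding is to the **nearest** integer (`round`), not the ceiling: at the
package's reference design point ($t = 3$, $\rho = 0.4$,
$\alpha = 10^{-8}$, power 0.8, $q = 0.005$) the exact solution is 5157.58,
reported as $n = 5158$; the single-visit design needs 8595.96 → 8596. The
three-visit design therefore genotypes $8596 - 5158 = 3438$ fewer subjects
at the cost of $3 \times 5158 - 8596 = 6878$ extra phenotype measurements.
These reference numbers are frozen in the acceptance tests and recomputed
by `scripts/acceptance.R`.

`power_at_n()` inverts the formula:
$\varphi = \Phi\!\big(\sqrt{n K \beta^2 t / (\sigma_p^2 (1 + (t-1)\rho))}
- z_{1-\alpha/2}\big)$.

## 3. The association engine

`fit_gls_longitudinal()` implements **iterated feasible GLS** with an
unstructured $t \times t$ covariance $\Sigma$:

1. Start from OLS (identity $\Sigma$).
2. Estimate $\Sigma$ from residual cross-products over pairwise-complete
   visits, dividing by the number of contributing subjects $n_{jk}$ (a
   maximum-likelihood-style divisor with no degrees-of-freedom
   correction).
3. Re-solve the GLS normal equations and repeat until
   $\max |\Delta\hat\Sigma| < 10^{-8}$ (cap: 50 iterations).

**Why iterated FGLS rather than REML?** The per-SNP model has a handful of
fixed effects and a single $t \times t$ covariance shared by all subjects;
with $n$ in the thousands the difference between ML and REML covariance
estimates is $O(p/n)$ and immaterial at GWAS scale, while the FGLS
iteration is simple, deterministic, and fast enough to run hundreds of
thousands of times. Standard errors are the usual GLS sandwich-free form
$(X'\Omega^{-1}X)^{-1}$ at the converged $\hat\Sigma$; consequently the
$t = 1$ special case reproduces `lm()` coefficients exactly and its
standard errors times $\sqrt{(n-p)/n}$ (the ML variance), and Wald tests
use the standard normal reference, as appropriate for design-stage sample
sizes in the thousands.

**Missing data.** Subjects are grouped by missingness pattern; within each
pattern the engine accumulates cross-products against
$\Sigma_{oo}^{-1}$ for the observed visit subset $o$. Design columns split
into subject-level columns (value repeated across visits) and time-slope
columns (value times $w_j$), so the per-pattern blocks reduce to three
scalars of $\Sigma_{oo}^{-1}$ — this is what makes a full scan cheap
(about 30 ms per fit at $n = 5158$, $t = 3$). The dense stacked-matrix
oracle in the test suite verifies the pattern-grouped solver to
$10^{-10}$. Non-positive-definite interim covariance estimates (possible
in degenerate or noise-free data) are repaired by adding a $10^{-8}$ ridge
with a warning.

Visit-level missingness is assumed ignorable given the model (the
simulator's dropout is MCAR); informative dropout is out of scope.

**Interactions.** `fit_interaction()` adds either a covariate-by-SNP
product column (e.g. sex × SNP) or a time-by-SNP slope column; the main
SNP effect is always retained.

## 4. The simulator

`simulate_cohort()` draws, in a fixed RNG order (genotypes, sex, age,
subject intercepts, polygenic draws, noise, dropout uniforms — so a seed
pins the cohort bit-for-bit):

* genotypes $g_i \sim \text{Binomial}(2, p)$,
* an optional polygenic term $u_i = \sigma_g(\sqrt{a}\, U +
  \sqrt{1-a}\, V_i)$ with a single shared factor $U$, giving every pair of
  subjects covariance $a\,\sigma_g^2$ — a compound-symmetric kinship
  $\Phi$ with off-diagonal $a$ (default 0.1) that never materialises an
  $n \times n$ matrix,
* monotone MCAR dropout: one uniform per subject retained at visit $j$ iff
  $u_i \le r_j$, so observed visits always form a prefix. The `"kare"`
  preset uses retention $(1, 7568/8842, 6675/8842)$, the package's
  reference three-visit cohort shape.

**Realism and limits.** The generator is deliberately the *model's own*
generative process plus the shared-factor polygenic extension: it is meant
for calibration and power studies, not for mimicking LD structure,
genotyping error, phenotype non-normality, or informative dropout. Power
estimates transfer to real cohorts only to the extent the
compound-symmetric residual model does.

`monte_carlo_power()` simulates replicate cohorts and counts Wald
rejections. Its default analysis, `"gls_independent"`, fits the standard
GLS ignoring the polygenic cross-subject correlation — matching what a
typical GWAS actually runs; the alternative `"gls_whitened"` removes the
rank-one shared factor by a Sherman–Morrison whitening and is the right
comparator when $\sigma_g^2 a$ is large. At the reference design point
(400 replicates) the independent analysis gives power $\approx 0.80$,
confirming the closed form. `monte_carlo_sample_size()` brackets the
target power geometrically and bisects to a 1 % grid.

## 5. Population structure

`ibs_matrix()` computes mean identity-by-state sharing from indicator
cross-products; `pca_scores()` double-centres the similarity matrix
(classical multidimensional-scaling convention) and returns eigenvector
scores scaled by $\sqrt{\lambda}$, which enter the association model as
covariates. Genomic control uses

$$
\lambda = \mathrm{median}(\chi^2_{\text{obs}}) / 0.45494,
$$

where 0.45494 is the median of the $\chi^2_1$ distribution, hard-coded to
five significant figures as the field-standard constant rather than
computed via `qchisq(0.5, 1)` (= 0.4549364…); the difference is below
$10^{-4}$ relative and the constant keeps reported $\lambda$ values
comparable with the wider literature. $\lambda$ is reported unclipped;
optional adjustment divides the observed statistics by $\lambda$.

## 6. Replication combination

Replication analyses are **direction-aware**. `one_sided_p()` converts a
two-sided replication p-value to one-sided form given the discovery
direction: $p/2$ if the effect sign is concordant, $1 - p/2$ if
discordant, $0.5$ at exactly zero. The package follows the common
discovery/replication convention of combining the discovery's two-sided
p-value with the replication's direction-aware one-sided p-value when the
user supplies them as such; the combiners themselves are agnostic to how
their inputs were produced.

* **Fisher:** $-2\sum \ln p_i \sim \chi^2_{2k}$.
* **Liptak (weighted Z):** $z = \sum w_i z_i / \sqrt{\sum w_i^2}$ with
  $z_i = \Phi^{-1}(1 - p_i)$. Default weights are $w_i = \sqrt{n_i}$:
  under equal per-subject information the non-centrality of $z_i$ grows as
  $\sqrt{n_i}$, and $\sqrt n$ weights maximise the power of the combined
  test. The package's reference two-cohort configuration uses
  $n = (8841, 3703)$.

## 7. Quality control

`qc_filter()` applies, in a fixed order: sample call rate → SNP call rate
→ Hardy–Weinberg ($\chi^2_1$) → MAF → per-sample heterozygosity → pairwise
IBS. The ordering is a package decision: sample-level missingness is
removed first so that per-SNP statistics are computed on the retained
cohort; relatedness is checked last, on the QC-passed marker set, and for
each flagged pair the lower-call-rate member is dropped (ties: the later
sample in file order). Default thresholds (0.95 call rates, HWE
$p > 10^{-6}$, MAF ≥ 0.01, heterozygosity ≤ 0.30, IBS ≤ 0.80) are all
overridable through `qc_thresholds()`. The genome-wide Bonferroni helper
`bonferroni_threshold()` returns $0.05/m$; at the package's reference
panel size of 352,228 markers this is $1.42 \times 10^{-7}$.

## 8. Problem sizes

The reference configurations wired into the tests and the acceptance
script — the $t = 3$, $\rho = 0.4$, $q = 0.005$, $\alpha = 10^{-8}$ design
point; the `"kare"` retention preset; the (8841, 3703) two-cohort
replication sizes; the 352,228-marker Bonferroni denominator — are the
package's own choices of a realistic population-cohort scale at which all
closed forms, simulations, and combination rules can be cross-checked
end-to-end within seconds on a single CPU.
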