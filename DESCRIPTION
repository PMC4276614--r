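Package: repgwas
Title: Design and Association Analysis for Repeated-Measures Genome-Wide
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing genome-wide association studies
    of quantitative traits measured repeatedly over time. Provides closed-form
    and Monte-Carlo sample-size and power calculations for a random-intercept
    phenotype model with an optional polygenic component, a generalized
    least-squares association engine with unstructured within-subject
    covariance, cross-sectional linear-regression scans, gene-by-environment
    interaction tests, principal-component adjustment for population
    structure based on the identity-by-state matrix, genomic-control
    inflation estimation, quality-control filters for genotype matrices, and
    direction-aware replication p-values combined by Fisher's and Liptak's
    (weighted-Z) methods. A synthetic-cohort generator reproduces the design
    of three-visit population cohorts with monotone dropout for simulation
    studies and test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
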