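Package: screenlink
Title: Linking Perturbations to Expression Phenotypes in Single-Cell
    CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of single-cell CRISPR screens
    (CROP-seq, Perturb-seq) that links each perturbation to expression
    phenotypes. Implements a dropout-aware robust rank aggregation test
    based on beta order statistics for single-marker ("virtual FACS")
    readouts, and a ridge-regression model estimating every
    perturbation's effect on every gene, both with permutation-based
    empirical p-values and Benjamini-Hochberg false discovery rate
    control. Includes 10x-style matrix input, quality-control and
    scaling preprocessing, gene-signature scoring, target-marker
    phenotype network construction, a cluster-enrichment baseline, and
    a negative-binomial screen simulator with dropout and multiplicity
    of infection structure for power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
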