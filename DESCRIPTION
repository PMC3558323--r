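Package: g2i
Title: Genomic Instability Scoring of Array-CGH Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring genomic instability from BAC-array comparative
    genomic hybridization (array-CGH) profiles of tumors. Provides penalized
    least-squares segmentation and smoothing of per-clone log2 ratios,
    gain/normal/loss (GNL) calling against the autosomal residual standard
    deviation, the two-parameter genomic instability index G2I (A, the mean
    per-arm fraction of altered clones, and N, the number of altered genomic
    regions) with three-grade classification, hierarchical clustering of GNL
    profiles into genomic archetypes, amplicon detection, association and
    survival statistics (odds ratios, chi-square tests, logistic regression,
    Kaplan-Meier/log-rank), a Welch t-test expression signature workflow, and
    a synthetic aCGH cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
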