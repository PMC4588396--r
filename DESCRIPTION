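Package: integraPC
Title: Integrative Copy-Number and Expression Subtyping of Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering and validating molecular
    subtypes of primary prostate cancer by joint modelling of somatic copy
    number and transcriptome data. Implements cis-eQTL feature selection
    (copy-number dosage effects on local transcript levels), a lasso-penalised
    joint latent-variable model fitted by EM with k-means subtype calling,
    model selection over cluster numbers and feature-set sizes,
    nearest-centroid transfer of subtypes to validation cohorts, per-subtype
    differential expression with empirical-Bayes variance moderation,
    Kaplan-Meier/logrank and Cox proportional-hazards prognostic evaluation
    with an events-per-variable guard, percent-genome-altered summaries, and a
    random-gene-signature resampling null for benchmarking prognostic
    signatures. A synthetic-cohort generator with recoverable ground truth
    supports testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    survival,
    sva,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
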