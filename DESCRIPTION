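Package: agewas
Title: Epigenome-Wide Analysis of Age Effects on DNA Methylation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An epigenome-wide association pipeline for chronological age on
    Illumina 450K-style beta values. Provides per-site linear modelling of
    methylation on age with sex and BMI covariates and Bonferroni-based
    hyper/hypomethylation classification, kernel-density mode counting of
    per-site beta distributions and their relation to nearby SNPs,
    PCA-based attribution of methylation variance to age, CpG island /
    shore / shelf and chromatin-state context with correlation-ordered
    binned enrichment curves, CpG-island ranking by the fraction of
    age-associated sites, integration with age trends in gene expression,
    and a synthetic-cohort generator with ground-truth tables for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
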