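Package: InvasionScreen
Title: Pooled CRISPRi Invasion Screen Analysis with Expression and
    Survival Follow-Up
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of pooled CRISPR-interference invasion screens and
    their downstream clinical follow-up. Converts sgRNA count matrices to
    normalized log2 invasion phenotypes, scores genes by the average
    phenotype of their top three sgRNAs times the negative log10
    Mann-Whitney p-value against non-targeting controls, and calls hits
    with a pseudo-gene empirical false-discovery rate. Downstream stages
    cover chromosome-subset CPM and RPKM normalization, quantile cohort
    stratification, Welch-t differential expression with
    Benjamini-Hochberg control, genome-wide Pearson correlation screening
    against a target gene, Kaplan-Meier and log-rank survival analysis,
    Cox proportional-hazards models with a two-segment linear-spline
    expression covariate selected by AIC knot search, and statistics for
    qPCR, transwell invasion, MTT and spheroid validation assays. Seeded
    generators produce synthetic screens, expression cohorts, survival
    cohorts and qPCR plates with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
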