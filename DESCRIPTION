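Package: somaticsieve
Title: Tumor-Only Somatic Versus Germline Variant Classification and
    Unbiased Tumor Mutational Burden Estimation
Version: 0.1.0
Authors@R:
    person("Somaticsieve", "Developers", email = "somaticsieve@example.org",
           role = c("aut", "cre"))
Description: Classifies variants from tumor-only whole-exome sequencing as
    somatic or germline with gradient-boosted decision trees trained on
    read-level, germline-database, COSMIC, mutational-spectrum and
    copy-number-aware features (including a 20-bin VAF histogram of
    neighboring informative SNPs), then uses the classifications to correct
    tumor mutational burden (TMB) estimates. Includes leave-one-out
    panel-of-normals construction, the pre-classification variant filters,
    category-specific posterior-probability thresholds, ensemble averaging,
    benchmark metrics (MCC, quantile-threshold ROC/PR), TMB concordance
    regression, a germline-database racial-bias report, and a synthetic
    tumor-cohort simulator so that the whole pipeline is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    BiocGenerics,
    SummarizedExperiment,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
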