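Package: missbench
Title: Benchmarking Missense Pathogenicity Predictions Against Clinical
    Variant Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking precomputed missense pathogenicity
    scores (AlphaMissense-style) against clinical variant annotations
    (ClinVar-style) over a gene panel. Provides protein-level variant
    matching by HGVS substitution, three-way score classification with
    the established benign/ambiguous/pathogenic thresholds, confusion
    tabulation at cohort and per-gene scope, estimation of sensitivity,
    specificity and false discovery rate with Wilson score intervals
    under two ambiguous-handling policies, ROC/PR summaries, Welch
    t-test discrimination of misclassified variants by population
    metrics (allele frequency, CADD, homozygote counts), rule-based
    flagging of suspected false negatives and false positives including
    hypomorph-profile comparison, and a seeded synthetic-cohort
    generator with closed-form expected metrics for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'classification.R'
    'concordance.R'
    'discrimination.R'
    'flagger.R'
    'ingest.R'
    'performance.R'
    'pipeline.R'
    'reference_data.R'
    'synthetic_data.R'
    'utils.R'
    'variant_model.R'
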