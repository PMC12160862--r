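Package: stromascape
Title: Stroma-Tumor Crosstalk Analysis for Single-Cell Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for dissecting stroma-tumor interactions in
    multi-sample single-cell RNA-seq cohorts, motivated by fibroblast-epithelial
    crosstalk in pancreatic ductal adenocarcinoma. Provides a synthetic cohort
    generator with planted ground truth, quality-control filtering and depth
    normalization, per-sample non-negative matrix factorization with Jaccard
    clustering of robust programs into meta-programs, module and rank-based
    signature scoring, simplified copy-number-variation profiling with a
    reference-percentile malignancy classifier, ligand-receptor interaction
    scoring with a permutation null and differential interaction networks,
    pseudobulk differential expression with preranked gene-set enrichment, and a
    clinical statistics layer (composite immunohistochemistry scoring,
    contingency tests, Kaplan-Meier/log-rank and Cox proportional hazards).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    survival,
    utils
Suggests:
    fgsea,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
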