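Package: mirmeso
Title: Integrated miRNA and mRNA Differential Expression Analysis for
    Two-Group Pleural Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Relative quantification of qPCR microRNA panels by the
    comparative cycle-threshold (delta-delta-CT) method with detection-limit
    truncation and censoring-aware reporting filters; differential mRNA
    expression by a variance-floored signal-to-noise statistic with an
    expression floor; Storey q-value multiple-testing correction; ROC/AUC
    biomarker evaluation with Youden-optimal cutoffs; and Bayesian
    model-based gene set analysis (MGSA) that integrates overexpressed genes
    with targets of downregulated microRNAs to score canonical pathways.
    Includes a synthetic-data generator that emulates an unbalanced
    case/reference design (18 vs 6 samples) with planted differential signal
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fgsea,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
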