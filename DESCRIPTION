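Package: methmark
Title: Urine DNA Methylation Biomarker Discovery and Diagnostic Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for DNA methylation biomarker studies of the
    kind used to develop urine-based bladder cancer tests: candidate gene
    selection from paired tumor/nontumor CpG-island microarrays (per-probe
    paired tests with Benjamini-Hochberg correction, fold-change and
    multi-probe gene enrichment filters), bisulfite-pyrosequencing
    methylation index (MtI) computation, quantitative methylation-specific
    PCR (qMSP) 40-delta-CT scoring with undetected-well imputation and run
    QC, and a diagnostics layer (ROC/AUC with DeLong-type confidence
    intervals, Youden-optimal cutoffs, exact binomial sensitivity and
    specificity intervals, Fisher exact association tables, Kruskal-Wallis
    group comparisons). Includes calibrated synthetic-data generators for
    paired arrays, pyrosequencing cohorts and qMSP cycle-threshold exports,
    so the full pipeline can be exercised end to end without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
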