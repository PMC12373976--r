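Package: dspgrade
Title: Compartment-Stratified Analysis of Digital Spatial Profiling Data
    Across Tumour Differentiation Grades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for segmented digital spatial profiling
    (DSP) count data from tumours with mixed histologic grades. Provides
    AOI-level technical quality control and negative-probe detection
    floors, 75th-percentile (Q3) normalization, marker-based epithelial
    contamination scoring and filtering, rank-based differential
    expression with a four-pattern monotone grade-trend classifier,
    single-sample gene-set enrichment (ssGSEA) scoring, hypergeometric
    over-representation analysis, within-ROI paired-compartment
    correlation, reference-based immune deconvolution with permutation
    significance filtering, and a composite pathway-based prognostic risk
    model (Cox regression, median stratification, Kaplan-Meier, log-rank,
    reverse Kaplan-Meier follow-up, ROC AUC). A synthetic cohort
    generator with planted ground truth supports calibration and
    parameter-recovery testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
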