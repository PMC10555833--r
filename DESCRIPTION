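Package: pqrShift
Title: Outlier Protein Quantitative Ratios and Correlation Shifts in
    Proteomic Sample Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens quantitative proteomics matrices for protein complex
    remodeling. For pairs of proteins known to form stable interactions, the
    log-ratio of their abundances (the protein quantitative ratio, PQR) is
    profiled in a reference sample group with robust statistics (median and
    median absolute deviation) and each test sample is scored with a modified
    z-score; samples exceeding |Mi| > 3.5 are outliers and their absolute
    scores are summed into a per-pair score. Significance is assessed against
    a randomized-background score distribution fitted with a
    matching-moments gamma, with Benjamini-Hochberg adjustment, followed by
    reference-variability and annotation filters and a redundancy resolution
    that reports each contributing protein through its single best pair. A
    companion differential-correlation screen classifies pairs that gain or
    lose co-expression between two sample groups, and complex-level tools
    test complex over-representation and scan median subunit expression for
    whole-complex shifts. A synthetic-data generator with known ground truth
    supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3),
    S4Vectors,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
biocViews: Proteomics, MassSpectrometry, DifferentialExpression,
    NetworkInference, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
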