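Package: cardioage
Title: Cardiac Ageing and Heart-Failure Phenotyping from MRI, Transcriptome and Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analytics for murine chronic heart failure and cardiac
    ageing studies. Segments left-ventricular time-volume curves into cardiac-cycle
    phases by exhaustive piecewise linear regression and derives hemodynamic indices
    (EF, CO, CI, ER, FR, phase durations, E/A ratio); computes myocardial radial and
    circumferential strain from SPAMM-tagged MRI via the harmonic-phase (HARP)
    method with eight-segment averaging and post-systolic strain indices; implements
    an ageing-gene classification of differential-expression results (TMM/cpm
    filtering, Welch-t DE with log2 fold-change and BH criteria, ageing/aged
    partition, Fisher over-representation, rank-normalised PCA); quantifies
    capillary morphometry and collagen fraction from segmentation masks; and
    evaluates ACE-activity and coronary-flow-reserve assay formulas. Ships seeded
    synthetic generators with ground-truth records for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
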