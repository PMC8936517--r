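Package: exscreen
Title: Ex Vivo Drug Sensitivity Screening: Plate QC, Dose-Response Fitting,
    DSS and Bliss Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for ex vivo drug-sensitivity screens of primary
    cancer cells on 384-well plates: plate quality control (Z-prime factor),
    control-based viability normalization, automated outlier screening,
    four-parameter log-logistic concentration-response fitting with a logistic
    fallback, IC20/IC50 extraction, a modified drug sensitivity score (DSS)
    integrated on the log-concentration axis, combination DSS for IC20-primed
    double and 4x4-matrix triple designs, Bliss-independence synergy scoring
    with a synergy-sum statistic, and cohort-level hierarchical clustering of
    drug-response profiles. Includes a plate simulator with known ground truth
    (log-logistic response surfaces, Bliss-shifted interactions, multiplicative
    lognormal noise) so that every stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    ggplot2,
    mclust,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
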