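Package: erpagree
Title: Single-Trial ERP Peak Detection and Between-Method Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for single-trial analysis of event-related potentials (ERPs)
    and for quantifying how well different detection methods agree. Includes a
    synthetic single-trial ERP simulator with known ground truth (graded
    stimulation intensities, logistic peak-presence model, 1/f-like background
    noise); a derivative-based peak detector with quadratic fuzzy-zone weighting
    (DRIV); a continuous Morlet wavelet filtering plus multiple-linear-regression
    peak estimator (WVLT); categorical agreement indices (overall, positive and
    negative percent agreement, chance agreement, Cohen's kappa with zero floor);
    quantitative agreement indices (Bland-Altman bias and limits of agreement,
    two-way absolute-agreement single-measure intraclass correlation, within-pair
    coefficient of variation); and group-level Friedman tests with
    Student-Newman-Keuls post hoc comparisons on mean ranks, including
    intensity-stratified analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
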