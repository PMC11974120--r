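Package: seegrftc
Title: Interictal SEEG Biomarkers and Outcome Prediction for
    Radiofrequency Thermocoagulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stereo-electroencephalography (SEEG)
    recordings acquired before and after SEEG-guided radiofrequency
    thermocoagulation (RF-TC). Implements windowed line-length and
    approximate-entropy biomarkers over four clinical frequency bands
    (0.5-250, 0.5-50, 50-80 and 80-250 Hz), average-reference montage,
    notch and band-pass preprocessing, within-subject normalization,
    directional nonparametric group comparisons with Bonferroni
    correction, and a two-level (contact then patient) surgical-outcome
    predictor based on a support vector machine with subset balancing
    and cross-validated model selection. A synthetic SEEG cohort
    generator with controllable band-specific effects supports
    end-to-end validation when clinical recordings are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    tibble,
    dplyr,
    tidyr,
    rlang,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
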