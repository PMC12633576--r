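Package: cmcmarkers
Title: Corticomuscular Coherence and Postural Sway Markers of Balance After Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for neuromechanical markers of
    balance and functional mobility. Generates synthetic cohorts of stroke and
    healthy participants performing a sway-referenced continuous balance task
    (EEG, bilateral lower-limb EMG, and centre-of-pressure traces), extracts
    Morlet wavelet corticomuscular coherence (CMC) measures with closed-form
    and Monte Carlo significance calibration, composite CMC indices (asymmetry,
    task modulation, band area under the curve), and posturography features
    (sway statistics, path length, sample entropy, 95 percent confidence
    ellipse area). A two-stage machine-learning procedure then performs
    classification-based feature selection (seven model families with Shapley
    attributions consolidated across seeds) followed by regression predicting
    Berg Balance Scale and Timed Up and Go scores, with Shapley rankings and
    Bonferroni-corrected Spearman feature analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    glmnet,
    xgboost,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma
Config/testthat/edition: 3
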