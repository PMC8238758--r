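Package: memroc
Title: Recognition-Memory ROC Models and Remember/Know Analysis for Image Memorability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how intrinsic image memorability shapes
    recollection and familiarity in recognition memory. Implements
    maximum-likelihood fitting of dual-process (DPSD) and unequal-variance
    (UVSD) signal-detection models to confidence-rating ROC data, with
    G-test goodness of fit, BIC model comparison and a preregistered-style
    winning-model rule; Snodgrass-Corwin-corrected hit and false-alarm
    rates, d-prime, empirical ROC/zROC points and trapezoidal AUC;
    scaled-difference statistics for remember/know and detailed/unfamiliar
    statements with one-sided JZS Bayes-factor t tests; ordinal
    (proportional-odds) regression predicting memorability quantile ranks
    from model parameters; and a generative DPSD/UVSD observer simulator
    with memorability-linked parameters for end-to-end testing without
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
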