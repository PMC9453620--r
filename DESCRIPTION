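Package: circphen
Title: Blood-Based Transcriptomic Circadian Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating transcriptomic circadian phenotyping in
    simulated cohorts. Generates multimodal synthetic cohorts (two-timepoint
    blood gene expression, evening saliva/plasma melatonin series, multi-day
    wrist actigraphy, morningness-eveningness questionnaire scores) that share
    a latent per-subject circadian phase offset; trains and applies a
    ridge-regression circadian clock on within-subject-normalized expression to
    obtain Transcriptomic Time, the signed Transcriptomic Angle, and a
    tolerance-accuracy curve with normalized AUC; computes dim-light melatonin
    onset by threshold calibration and linear interpolation; derives
    nonparametric rest-activity rhythm metrics (M10, L5, amplitude, interdaily
    stability, intradaily variability) and diary-anchored sleep variables; and
    quantifies agreement between modalities with Pearson and partial
    correlations, z-scored Bland-Altman limits of agreement, and group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
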