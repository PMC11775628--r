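Package: stnlfp
Title: Subthalamic Local Field Potential Analysis of Conflict Control in the Simon Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for intraoperative subthalamic nucleus
    (STN) local-field-potential analysis of conflict control during the Simon
    task. Implements microelectrode signal conditioning (three-channel
    demeaning, decimation to 1000 Hz, detrending, band-pass and notch
    filtering), Morlet wavelet time-frequency decomposition with a linear
    cycle ramp, theta and low-beta band power, trial-wise baseline
    normalization (decibel and z-score) with a paired-t trial inclusion test,
    response-locked epoching into four time bins, distributional behavioral
    analyses (delta plots, conditional accuracy functions), linear mixed-model
    contrasts on log band power, and baseline-power/behavior Spearman
    correlations. A synthetic-data generator emulates the recordings and
    behavior of the intraoperative study design so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
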