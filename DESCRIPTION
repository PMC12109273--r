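Package: gvstrack
Title: Tracking-Error Analysis for Amplitude-Modulated Galvanic Vestibular Stimulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing visuomotor pursuit-tracking experiments in
    which participants track a Lissajous-driven target while receiving
    amplitude-modulated galvanic vestibular stimulation (GVS). Provides the
    stimulus bank and waveform synthesis, Lissajous target and cursor
    perturbation generators, a synthetic-cohort simulator with planted
    stimulus effects, the Hilbert-regression tracking-error statistic with
    sub-trial segmentation, configuration and stimulus comparison metrics
    including individualised-stimulus selection and performance-improvement
    percentages, and the statistical layer (linear mixed-effects
    configuration contrast, paired Wilcoxon signed-rank test, and
    Benjamini-Hochberg false-discovery-rate adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
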