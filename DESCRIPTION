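Package: saccadecs
Title: Saccade-Based Adaptive Contrast Sensitivity Testing and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop simulation engine for objective peripheral
    contrast-sensitivity testing with reflexive saccades. Implements the
    QUEST+ Bayesian adaptive procedure over a threshold-by-slope grid with
    expected-entropy stimulus placement, live classification of saccadic
    responses from gaze streams (fixation-window enforcement, atan2
    direction, +/-22.5 degree acceptance cone), balanced randomized trial
    scheduling with catch trials and blink re-randomization, a statistical
    simulated observer (Weibull detection, contrast-dependent saccade
    latency, fixational false positives, 4AFC guessing), maximum-likelihood
    cumulative-Weibull psychometric fitting, log-parabola contrast
    sensitivity function fitting, and method-agreement analysis (Pearson
    correlation and Bland-Altman limits of agreement).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
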