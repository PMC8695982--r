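Package: alphasurf
Title: Virtual Wave-Surfing Motor Learning: Task Simulation, Kinematic
    Metrics, and Alpha-Band Topographic Randomization Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how task instructions shape motor learning in a
    virtual wave-surfing task and how alpha-band attentional networks change
    with training. Provides a deterministic closed-loop simulator of the
    surfing task (pitch-dependent acceleration, joystick-to-torque steering,
    parameterized agent skill), trial- and participant-level kinematic
    performance metrics with Hit/Missed and obstacle-avoidance outcome
    classification, the behavioural hypothesis-test battery (Wilcoxon
    signed-rank, Kruskal-Wallis with Holm-corrected Mann-Whitney post-hocs,
    ANOVA with Tukey-Kramer, assumption gates, Cohen effect sizes), a
    synthetic epoched-EEG generator with planted topographic effects, the
    temporal-spectral-evolution (TSE) alpha-strength transform, and a
    randomization-based mixed-design topographic ANOVA (TANOVA) with a
    run-length critical-duration correction for multiple testing across
    time, pairwise contrast tests and electrode t-maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
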