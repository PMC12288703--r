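Package: jitaisim
Title: Simulation and Randomization Inference for Multiple-Baseline
    Just-in-Time Adaptive Intervention Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing single-case
    AB multiple-random-baseline trials of just-in-time adaptive
    interventions (JITAIs) delivered through ecological momentary
    assessment (EMA). Models the trial skeleton (study length, prompt
    schedule, randomized baseline lengths), threshold-band decision
    rules mapping momentary stress and forecast busyness to recommended
    exercises, and a synthetic cohort generator with AR(1) momentary
    stress, phase-level and acute intervention effects, and per-prompt
    non-response. Analysis covers per-protocol filtering, day-level
    aggregation, individual and combined (across-case) randomization
    tests with exhaustive or Monte Carlo null distributions, mixed-model
    pre/post exercise effects, paired questionnaire effects with Cohen's
    dz, and Monte Carlo power and type-I-error estimation for the
    combined test.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
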