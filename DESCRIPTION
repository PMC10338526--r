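Package: habitometry
Title: Operant Schedule Simulation, Fiber-Photometry Preprocessing, and
    Decoding of Goal-Directed Versus Habitual Reward Seeking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pallidostriatal calcium dynamics during
    goal-directed (random-ratio) and habitual (random-interval) reward
    seeking. Simulates operant sessions under fixed-ratio, random-ratio and
    random-interval schedules together with GCaMP-like fluorescence traces;
    computes three-stage dF/F (sliding mean, preceding-minimum baseline,
    exponentially weighted smoothing) and detects supra-threshold calcium
    events; aligns dF/F to behavioural events, averages by event class and
    quantifies within-session trends across decile blocks; decodes schedule
    condition with a linear support-vector machine under repeated balanced
    undersampling and stratified k-fold cross-validation; and provides
    reward-devaluation and nonparametric group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    data.table,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
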