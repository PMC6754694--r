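Package: hrvband
Title: Three-Band Heart Rate Variability Biofeedback and Study-Protocol Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for heart rate variability (HRV) biofeedback
    research built around beat-by-beat interbeat-interval (IBI) streams.
    Implements ingestion, artifact editing and quality checks for IBI series;
    three band-limited ln-variance HRV measures (respiratory sinus arrhythmia,
    low-frequency, and wideband) computed per epoch and as a 2-second streaming
    feed; a paced-breathing pacer waveform; an Eriksen flanker cognitive
    stressor with trial scheduling and scoring; segmented training-session
    orchestration with a calibrated biofeedback meter; a yearlong study
    calendar with incentive evaluation, nightly fulfillment and cohort
    compliance reporting; segment-level descriptive and inferential statistics;
    and a synthetic IBI/cohort simulator so every stage is testable without
    hardware.
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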