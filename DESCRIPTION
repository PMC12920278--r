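Package: oxipulse
Title: Pulse-Oximetry Screening of Obstructive Sleep Apnea from PPG and SpO2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for screening moderate-to-severe
    obstructive sleep apnea (OSA) from pulse-oximeter signals. Raw finger
    photoplethysmography (PPG) and oxygen saturation (SpO2) waveforms are turned
    into beat series (pulse-to-pulse intervals and pulse wave amplitudes),
    segmented into non-overlapping 60-second windows, summarised by 37
    time-domain, frequency-domain and entropy features, and classified with
    support vector machines under subject-grouped nested cross-validation.
    Per-subject apnea-hypopnea index (AHI) estimates and AHI >= 15 screening
    decisions are derived from the per-segment predictions. A synthetic
    polysomnography generator with known ground truth (arousal-locked pulse wave
    amplitude drops, pulse interval shortening, and post-event desaturations)
    supports testing every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    pracma,
    ranger,
    e1071,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tidyr,
    withr
Config/testthat/edition: 3
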