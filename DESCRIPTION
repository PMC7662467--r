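Package: apneascreen
Title: Portable Sleep Apnea Screening from Respiratory Effort, Oximetry and ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end screening pipeline for obstructive and central sleep
    apnea and hypopnea from a portable sensor set: two triaxial accelerometers
    (thoracic and abdominal respiratory effort), pulse oximetry (SpO2) and a
    single-lead ECG. Implements respiration-bearing axis selection,
    synchrosqueezing-transform instantaneous-amplitude estimation,
    amplitude-ratio / frequency-ratio and SpO2 descriptors, an LSTM recurrent
    network for per-step OSA/CSA/HYP/NOR event classification, oxygen
    desaturation detection, a convolutional sleep-wake classifier on
    instantaneous heart rate, event extraction, apnea-hypopnea index (AHI)
    scoring with severity grading, and a fully labelled synthetic
    overnight-recording simulator for training and validation without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
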