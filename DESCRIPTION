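Package: errtheta
Title: Midfrontal Theta Error-Monitoring Analysis for a Saccadic Go/No-Go
    Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying error monitoring
    with combined eye tracking and EEG in a facial-cue go/no-go saccade task.
    Generates counterbalanced pro-/anti-/no-go sessions, simulates gaze traces
    (120 Hz) and multichannel EEG (1000 Hz) with planted saccades, errors and
    condition-dependent midfrontal theta bursts; detects saccades with a
    displacement-threshold algorithm (4.04 degree amplitude, 15 ms minimum
    duration, 80 percent vertical rule, central-area logic); classifies trials
    against the instruction; preprocesses EEG (zero-phase FIR 0.05-45 Hz,
    500 Hz resample, average reference, spherical-spline interpolation),
    epochs around saccade onset and computes ERN/Pe window amplitudes and
    baseline-normalised 4-8 Hz power; and decides correct-versus-error
    differences with a 20-subsample class-balanced Wilcoxon replication
    procedure with pro-saccade proportion matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
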