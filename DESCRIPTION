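Package: somnoscope
Title: Sleep Architecture and Circadian Activity Analysis for Rodent EEG/EMG Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing mouse polysomnography and locomotor-activity
    studies: per-epoch EEG/EMG spectral features (band power, slow-wave
    activity, sample entropy, detrended fluctuation analysis), rule-based
    vigilance-state scoring into wake/NREM/REM on a 10-second epoch grid,
    hypnogram architecture statistics (episode durations and counts,
    state-transition probability matrices, REM-sleep latency distributions,
    slow-wave-activity time courses), chi-square periodogram rhythm metrics
    for wheel-running and infrared activity counts, and the group-comparison
    battery commonly used for genotype studies (unpaired t, two-way ANOVA
    with Sidak or Fisher-LSD post hoc, Shapiro-Wilk and Brown-Forsythe
    checks).  Includes a synthetic-data generator - phase-switched Markov
    vigilance kinetics, state-conditioned EEG/EMG synthesis and an entrained
    or free-running activity model - with wild-type and mutant presets for
    end-to-end validation, plus minimal EDF signal input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
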