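Package: somnoscore
Title: Rodent Polysomnography Simulation, Featurization and Automated Sleep Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated vigilance-state analysis of rodent EEG/EMG
    telemetry. Provides a seeded synthetic telemetry generator (Markov
    state-switching on a 10-second epoch grid, state-dependent band-limited
    EEG, EMG tone, cage activity and core body temperature under a light/dark
    schedule, with optional treatment effects), DFT-based per-epoch
    featurization into 40 spectral channels plus EMG and activity (42 features
    per epoch, 210 per five-epoch moving window), a fully connected
    210-512-3 neural network classifier of wake/NREM/REM with stratified
    splitting, training-set oversampling and standard evaluation metrics,
    hypnogram architecture analytics (bouts, transitions, onset latencies,
    binned durations, treatment contrasts), and state- and phase-resolved
    EEG band-power spectra. Recordings round-trip through European Data
    Format (EDF) plus a delimited-text epoch sidecar.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
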