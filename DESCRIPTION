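Package: eegmi
Title: Spectral Analysis of Motor-Imagery EEG with Wavelet Artifact Attenuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multi-channel motor-imagery
    EEG experiments. Generates task-structured synthetic EEG (1/f background,
    band-limited alpha and beta oscillations with condition-dependent gains on
    motor-area channels, line noise, transient blink and muscle artifacts),
    preprocesses 1-minute trials (channel selection, trimming, polyphase
    downsampling, zero-phase Butterworth band-pass, 1-s epoching), attenuates
    artifacts with a tunable wavelet-domain filter (db4 discrete wavelet
    transform, interquartile-range-driven thresholds, piecewise-linear
    coefficient attenuation), and computes Welch periodograms, Simpson-rule
    alpha/beta band powers, spectral entropy, channel-paired Wilcoxon
    signed-rank tables and interpolated scalp maps, with min-max normalisation
    pooled across a subject's experimental tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
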