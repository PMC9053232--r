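Package: somnoloop
Title: Closed-Loop Auditory Slow-Wave Stimulation Simulator and Sleep EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and analysis toolkit for closed-loop
    phase-targeted auditory stimulation of sleep slow waves. Generates
    synthetic single-channel polysomnography with ground-truth hypnogram and
    slow-oscillation phase, re-implements a wearable stimulation device's
    real-time decision stack (band-power NREM gating, first-order
    phase-locked-loop up-phase targeting, reinforcement vetoes, adaptive
    volume control, continuous and 6-s windowed scheduling), and provides the
    offline spectral pipeline used to quantify the stimulation effect: Welch
    spectra of 6-s epochs, low-frequency slow-wave activity (0.75-1.25 Hz),
    ON-OFF window contrasts with stimulation-count binning, slow-wave energy,
    evoked responses, arousal detection, night-level quality control, and the
    small-sample statistics for responder classification (repeated-measures
    correlation, cross-validated linear discriminant analysis, t and
    chi-square worked examples).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
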