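Package: vigilstate
Title: Vigilance-State Scoring, Slow-Wave and Pupillometric Analysis of
    Rodent Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for characterising dissociated vigilance
    states in rodent sleep recordings. Provides rule-based 4-s-epoch scoring of
    wake, NREM and REM sleep from frontal/occipital EEG and EMG with
    micro-arousal refinement and artefact flagging; per-epoch Hanning-window
    power spectra at 0.25 Hz resolution with band-power time courses, aperiodic
    (1/f) spectral-slope fitting and Tort-style phase-amplitude modulation
    index; zero-phase Chebyshev type II slow-wave filtering, local field
    potential slow-wave detection with amplitude criteria and peri-wave
    multi-unit OFF-period profiling; pupil-diameter estimation from
    pose-estimation keypoints with likelihood filtering and pupil-EEG
    correlation; sleep-architecture endpoints (REM latency, time in state,
    cumulative curves, slow-wave-activity dynamics, per-bin spectral
    contrasts); and a fully synthetic study generator (EDF signals, spike
    lists, pose CSVs, ground-truth hypnograms) so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
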