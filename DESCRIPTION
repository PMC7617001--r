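Package: pwmtms
Title: Pulse-Width-Modulated Transcranial Magnetic Stimulation: Waveforms,
    Thresholds and Motor-Evoked-Potential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coil voltage and current waveforms of a
    conventional monophasic magnetic stimulator (underdamped RLC discharge
    with a freewheel decay path) and their five-level pulse-width-modulated
    (PWM) approximation, compares the two by harmonic spectral analysis,
    predicts neural activation thresholds with a calibrated surrogate
    neuron bank driven by the induced coil-current rate of change, and
    provides a full motor-evoked-potential (MEP) analysis pipeline
    (peak-to-peak measurement, resting-motor-threshold staircase, onset
    latency detection, sigmoid input-output curve fitting and
    repeated-measures statistics) exercised end-to-end on a seeded
    synthetic within-subject two-device cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
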