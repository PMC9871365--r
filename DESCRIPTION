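Package: stressmux
Title: Multimodal Cold-Pressor Habituation Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of repeated cold-pressor (versus warm
    water control) sessions instrumented with ECG, impedance cardiography,
    continuous blood pressure, pupillometry and EEG. Provides a synthetic
    session generator with known ground truth, beat-level cardiovascular
    feature extraction (heart rate, pre-ejection period, left-ventricular
    ejection time, stroke volume, cardiac output, mean arterial pressure,
    total peripheral resistance), trailing-window high-frequency heart-rate
    variability, pupil and EEG band-power reduction, and a pointwise
    permutation-null repeated-measures ANOVA framework with
    interaction-gated habituation contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
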