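Package: zfecg
Title: Zebrafish Electrocardiogram Simulation, Delineation and Drug-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing single-lead electrocardiograms of adult
    zebrafish: zero-phase FIR band-pass preprocessing, adaptive-threshold
    R-peak detection, beat segmentation with template averaging, P/QRS/T
    fiducial delineation, interval measurement with Fridericia heart-rate
    correction of the QT interval, and paired pre/post drug-effect analysis
    (fold change, paired t-test, dose-response tables, atrioventricular-block
    classification).  A synthetic zebrafish ECG generator with a ground-truth
    annotation channel emulates the acquisition (600 samples/s, 80 Hz digital
    low-pass), zebrafish beat morphology and rhythm, gill-movement and
    AC-line noise, and drug scenarios, so the whole pipeline is testable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
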