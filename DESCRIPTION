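Package: neoseize
Title: Simulation and Quantitative Analysis of Neonatal EEG Seizure
    Morphology Under Phenobarbital
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how phenobarbital changes the morphology of
    neonatal electrographic seizures and whether those changes affect
    automated seizure detection. Provides a synthetic multichannel
    neonatal EEG generator with graded background abnormality and five
    ictal discharge morphologies, a ten-feature seizure quantification
    scheme (peak amplitude, rhythmicity, background grade, onset/peak
    morphology, duration, frequency variability, morphology change,
    channel involvement at onset and peak), an SVM-based epoch
    classifier with sigmoid probability output and thresholded event
    detection, event-based detection scoring, and paired nonparametric
    cohort statistics (per-subject summaries, weighted-average
    percentiles, Wilcoxon signed-rank with exact and tie-corrected
    asymptotic paths). Includes EDF and annotation text I/O and a
    fixture path that recomputes published group statistics from
    per-subject values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    e1071,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
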