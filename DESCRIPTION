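Package: fxseeg
Title: EEG Biomarker Simulation and Naive Bayes Classification for Fragile X Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving resting-state spectral EEG variables (absolute and
    relative band power, peak alpha frequency) and auditory-chirp time-frequency
    variables (inter-trial phase coherence and single-trial power via Morlet
    wavelets), classifying diagnostic groups and genetically mediated subgroups
    of Fragile X Syndrome with a Gaussian naive Bayes classifier under a
    70/30 holdout, full-dataset AUC and 10-fold cross-validation protocol, and
    simulating multichannel EEG and feature tables with known ground truth from
    bundled cohort summary statistics so every pipeline stage is testable
    without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
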