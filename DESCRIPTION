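Package: episeizer
Title: Epileptic Seizure Detection from Single-Channel EEG via Sub-Band
    Entropy Features and Ensemble Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects epileptic seizures in single-channel EEG recordings.
    Signals are decomposed with a five-level Daubechies-4 discrete wavelet
    transform; approximate entropy and sample entropy are computed on the
    d3/d4/d5 detail sub-bands (3-25 Hz, the band of ictal rhythms) to give
    six features per record; features are ranked by one-way ANOVA F and
    reduced by forward sequential selection; a majority-vote ensemble of a
    least-squares SVM (linear kernel), 3-nearest-neighbours and Gaussian
    naive Bayes classifies records as ictal or interictal, evaluated by
    stratified 10-fold cross-validation. Includes a reader for Bonn-style
    one-sample-per-line ASCII signals and a synthetic ictal/interictal EEG
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
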