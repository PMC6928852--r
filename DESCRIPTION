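Package: ecgvote
Title: Inter-Patient ECG Heartbeat Classification with Ensemble Empirical
    Mode Decomposition Features and Product-Rule Classifier Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for AAMI-convention heartbeat classification from
    single-lead ECG. Implements the full chain: denoising (moving average,
    1 Hz high-pass, 45 Hz Butterworth low-pass), 300-sample beat
    segmentation around annotated R peaks, improved complete ensemble
    empirical mode decomposition (ICEEMD) of each beat, nonlinear features
    (Shannon, log-energy and norm entropies plus second-, third- and
    fourth-order cumulants) from the first six modes, and a product-rule
    voting ensemble of naive Bayes, linear and quadratic discriminant, and
    information-gain decision-tree classifiers (plain and consolidated).
    Evaluation follows the AAMI inter-patient scheme (DS1/DS2 record
    split) with the class-specific false-positive conventions used in the
    arrhythmia literature. A seeded synthetic multi-class ECG generator
    exercises every stage without access to the MIT-BIH database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
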