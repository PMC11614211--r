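Package: seegDecode
Title: Decoding Stimulus Periods from Intracranial EEG with PCA and Linear SVM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A per-contact decoding pipeline for stereotactic EEG (sEEG)
    recordings from a numerical-cognition task. Builds Morlet time-frequency
    features with an appended band-passed voltage trace, classifies stimulus
    versus inter-trial epochs with cross-validated PCA plus a linear support
    vector machine, assesses significance against an exact binomial null,
    back-projects classifier weights into time-frequency space
    (eigenspectrograms) with one-sample sign-flip cluster permutation tests,
    and aggregates contact results into group-level spectral feature maps.
    Includes a synthetic local-field-potential generator with 1/f background
    noise and planted band-limited effects so the full pipeline is testable
    end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
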