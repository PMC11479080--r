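Package: emergeeg
Title: Synthetic EEG Sessions and Online Emergency Detection with
    Hierarchical Discriminant Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying event-related-potential (ERP) based detection
    of emergencies from operator EEG.  Generates paradigm-faithful synthetic
    multichannel EEG sessions (Gaussian-envelope ERP templates, rhythmic and
    broadband background noise, ocular and burst artifacts), implements a
    causal preprocessing chain (anti-aliased downsampling, trailing-window
    baseline correction, seeded FastICA with EOG-guided component rejection,
    artifact subspace reconstruction, Butterworth band-pass filtering),
    hierarchical discriminant component analysis (HDCA) with stratified
    cross-validation and linear comparators, ERP peak statistics (Wilcoxon
    rank-sum, sign-flip permutation paired t-tests, Benjamini-Hochberg FDR),
    and a simulated-streaming online detection protocol scored by recall,
    false alarm rate, accuracy and response time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    MASS,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
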