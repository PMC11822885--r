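Package: intentdecode
Title: Causal Decoding of Speech-Production Intent from Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting speech-production intent in
    electrocorticography (ECoG) and stereo-EEG recordings. Provides delay-corrected
    high-gamma band-power extraction (causal linear-phase FIR filtering with exact
    group-delay correction, Hilbert-transform envelopes), construction of class-labelled
    feature windows around voice onset, offset-swept RBF-SVM decoding of speech intent
    versus silence or an instructed-delay control with permutation-based empirical chance
    distributions and Benjamini-Hochberg false-discovery-rate correction, demixed principal
    component analysis (dPCA) of intent versus silence state-space trajectories, and
    k-means clustering of event-locked envelope dynamics into production-like and
    perception-like electrode groups. A seeded synthetic-recording generator with 1/f
    background, line noise, common-mode noise, and role-specific high-gamma modulation
    makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
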