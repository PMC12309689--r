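Package: rhythmRSA
Title: Frequency-Domain Representational Similarity Analysis for Rhythm
    Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting categorical structure and underlying rhythm
    prototypes in continuous periodic response signals such as finger-tapping
    records and EEG. Implements frequency-domain representational similarity
    analysis (fRSA): frequency-tagging feature extraction at harmonics of a
    rhythmic pattern repetition rate, representational similarity matrices
    built from complex Fourier coefficients, partial Spearman comparison
    against two-category theoretical models with permutation and bootstrap
    inference, an intertap-interval behavioral pipeline with sigmoid versus
    linear categorization fits, and a prototype-similarity analysis locating
    integer-ratio attractors in magnitude spectra. Ships synthetic generators
    for tapping and EEG-like data with known categorical ground truth, plus
    readers and writers for EDF, BrainVision, WAV and delimited signal tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
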