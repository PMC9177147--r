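Package: boundarypattern
Title: Boundary-Locked Activation Pattern Analysis for Movie Encoding and Free Recall fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing transient cortical activation patterns evoked by
    boundaries between mental contexts in naturalistic fMRI experiments in which
    subjects watch a series of short movies and later recall them aloud in an order
    of their choosing. The package extracts offset-locked boundary and mid-movie
    non-boundary spatial patterns from surface-sampled BOLD time series, computes
    between-movie and between-phase (encoding vs. recall) pattern similarity with
    parcel-wise conjunction inference, time-locked pattern dynamics around movie
    onsets and offsets, within-movie versus between-movie boundary templates, and
    audio-silence confound controls based on Hilbert-envelope regressors. A
    synthetic-experiment generator with planted spatial patterns, a double-gamma
    haemodynamic response model, and configurable noise makes every analysis stage
    testable without access to real neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
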