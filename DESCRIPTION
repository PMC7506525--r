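Package: aecnet
Title: Amplitude-Envelope Connectivity Networks from Band-Limited Node Timecourses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for resting-state oscillatory connectivity analysis of
    atlas-node timecourses: band-pass filtering into canonical frequency bands,
    symmetric multivariate orthogonalization for signal-leakage correction,
    Hilbert amplitude envelopes, envelope correlation with Fisher transform and
    per-subject normalization, combined-frequency connectomes, group
    dysconnectivity statistics (rank-consensus edge selection, Welch tests with
    max-statistic permutation correction, split-half sign-consistency
    resampling, covariate regression), per-subject weighted graph construction
    with six nodal metrics, and cross-validated linear support-vector
    classification of group status with permutation p-values. Includes a
    synthetic cohort generator with controlled envelope-correlation structure,
    linear leakage, group effects at designated edges, and covariates, so the
    full pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    igraph,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
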