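Package: srquant
Title: Specificity-Ratio Quantification and Statistics for Antibody
    Validation Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies antibody specificity in multi-channel fluorescence
    microscopy. Simulates ground-truth-annotated fields of cells with
    lognormal per-cell intensities, extracts per-cell mean intensities from
    maximum projections, computes the per-cell specificity ratio (antibody
    signal in reporter-positive cells relative to the mean of at least 20
    reporter-negative cells in the same field), and performs nonparametric
    inference: Mann-Whitney tests, Hodges-Lehmann shift estimates with
    distribution-free 95 percent confidence intervals, a log-variance
    knockout specificity check, and a Monte Carlo power and sample-size
    simulation for lognormal specificity-ratio data. Also scores percent
    identity of antibody immunogen regions against orthologue sequences.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    igraph,
    Biostrings,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
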