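Package: bioticrange
Title: Presence-Background Distribution Models with Biotic Range-Limit
    Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to test whether a biotic interaction (the presence of a
    resource species) limits a focal species' geographic range beyond what
    climate predicts.  Implements a from-scratch presence-background
    maximum-entropy model with L1 regularization, feature expansion
    (linear, quadratic, product, hinge, categorical), percent contribution
    and permutation importance; occurrence-record effort filtering, 1-km
    spatial thinning, k-fold partitioning and background sampling;
    distance-buffered binary resource layers; a six-index, threshold-sweep
    model evaluation suite with emphasis on commission (overprediction);
    and a synthetic-landscape generator so the full abiotic versus
    abiotic-plus-biotic model comparison is testable end to end without
    external raster downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
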