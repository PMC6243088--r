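Package: conneval
Title: Connectivity-Aware Evaluation of Connectomics Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates electron-microscopy (EM) connectomics segmentations
    against ground truth or against each other. Implements variation of
    information and Rand indices with per-body decompositions, a
    synapse-aware connectivity-correctness metric based on one-to-one
    segment assignment, fragmentation scores, and ground-truth-free orphan
    and autapse statistics. All supervised metrics are computed from sparse,
    mergeable blockwise contingency tables so arbitrarily large label
    volumes can be processed in pieces. Includes a seeded synthetic-scene
    generator with split, merge and boundary-shift corruption operators for
    known-answer testing, a zarr-backed volume reader/writer, and a
    command-line driver producing JSON evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
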