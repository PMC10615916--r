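Package: smdistance
Title: Sensorimotor Distance Between Concepts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Grounded semantic dissimilarity between word concepts computed
    from 11-dimensional sensorimotor strength ratings (six perceptual
    modalities and five action effectors, each rated 0-5). Implements cosine
    distance as the principal measure plus correlation, Euclidean,
    Minkowski-3 and Mahalanobis distances; streaming summaries of the full
    unordered pair space (moments, extreme pairs, histograms) without
    materialising the pair matrix; exact nearest-neighbour search; Sammon
    stress minimisation for 2-D layouts; polar-profile export; evaluation
    against human similarity benchmarks (coverage, zero-order correlations,
    hierarchical incremental R-squared, best-subset ranking, concreteness
    splits); synthetic norms and benchmark generators with known ground
    truth; and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
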