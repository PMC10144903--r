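Package: markerscore
Title: Marker-Based Cell-Type Scoring, Annotation and Integration of
    Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free standardization, annotation and integration of
    single-cell RNA-seq data through marker-weighted cell-type score
    matrices. Identifies ranked cell-type markers from annotated reference
    data with an ensemble of differential-expression tests combined by
    robust rank aggregation or Lancaster p-value combination, converts
    expression to a low-dimensional cell-type score representation (raw or
    percentile-thresholded TF-IDF variants), transfers labels by consensus
    Louvain over-clustering, flags unseen cell types with a centroid-based
    certainty score, and evaluates annotation and batch mixing (accuracy,
    macro F1, rescaled silhouette, batch-mixing entropy, ARI, NMI). Includes
    a seeded multi-batch negative-binomial simulator with planted markers so
    the full workflow is testable without external atlases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    cluster,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
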