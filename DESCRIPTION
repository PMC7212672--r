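Package: timedrift
Title: Detection and Correction of Sampling-Time Artifacts in Single-Cell
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate, detect, quantify, and correct technical
    artifacts introduced by delayed sample processing (time between blood
    draw and cryopreservation) in single-cell RNA-seq experiments.
    Includes a negative-binomial count simulator with planted
    time-dependent degradation and ground truth, hashtag-oligo (HTO)
    demultiplexing by centered log-ratio normalization with k-medoids
    background estimation, quality-control filters and size-factor
    normalization, rank-based differential expression to derive a
    sampling-time gene signature, expression-bin-matched module scoring
    and logistic classification of affected cells, regression-based
    correction, and mixing/variance diagnostics (kBET acceptance rates,
    pairwise proportionality, per-gene r2 attribution, PC-weighted
    variance fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    cluster,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
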