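Package: domemap
Title: Spatial Multi-Omic Mapping of Gut-Associated Lymphoid Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A verifiable pipeline for the spatial analysis of gut-associated
    lymphoid tissue (GALT) across suspension mass cytometry, imaging mass
    cytometry, spot-level spatial transcriptomics and pixel colocalization.
    Provides a synthetic tissue generator with known ground truth (zoned
    follicle geometry, lognormal marker models, spillover, negative-binomial
    spot counts, two-channel rasters), SPADE-style density-normalised
    clustering trees with rule-based subset bubbles, per-image gating with
    mutual exclusion and random-forest label propagation, non-negative
    least-squares spillover compensation, Harmony-style batch integration,
    distance-to-epithelium statistics, Potts-prior Markov chain Monte Carlo
    spot clustering with cluster-number tuning, region differential expression
    with log-fold-change and minimum-fraction thresholds, and gene-gene
    Spearman correlation matrices with Holm adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    mgcv,
    mclust,
    randomForest,
    pracma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
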