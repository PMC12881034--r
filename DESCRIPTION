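Package: longigp
Title: Longitudinal Genomic Prediction of Multi-Trait Developmental Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction of multi-trait time-resolved
    phenotypes in inbred plant populations. Implements dynamics-based
    prediction (dynamicGP): genotype-specific Schur-based dynamic mode
    decomposition of trait-by-time matrices yields low-rank operator
    building blocks that are treated as pseudo-traits, predicted from
    genome-wide markers with ridge-regression BLUP or a latent-factor
    multi-trait model, reassembled into a per-genotype linear operator and
    propagated iteratively or recursively over the time series. Also
    provides direct multi-variate configurations (single-trait models per
    trait-time pair, whole-series latent-factor models with CV1/CV2-style
    use of secondary traits), CV3 forecasting of unseen time points,
    snapshot and longitudinal accuracy assessment with significance
    thresholding, developmental-trajectory roughness and convexity
    statistics, Mantel-network trait pre-selection, and a synthetic
    MAGIC-like data generator with known dynamics ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    vegan,
    jsonlite
Config/testthat/edition: 3
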