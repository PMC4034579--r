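Package: salicsd
Title: Visual Saliency from Adaptive Sparse Coding and Color Region
    Covariances
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Bottom-up visual saliency estimation from a dual image
    representation: per-image (adaptive) ICA sparse coding of color
    patches and nonlinear color region-covariance descriptors with a
    sigma-point first-order embedding.  Both representations are scored
    by a distance-weighted center-surround dissimilarity operator and
    fused, with Gaussian smoothing, into a single saliency map.  Includes
    fixation-prediction metrics (rank/ROC AUC, shuffled AUC), salient
    object metrics (Dice similarity curves and their peak), seeded
    generators for pop-out psychophysical stimulus arrays and
    center-biased synthetic fixations, and image/fixation/mask I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ica,
    jpeg,
    methods,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'salicsd-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'geometry.R'
    'csd.R'
    'covariance.R'
    'ica.R'
    'metrics.R'
    'sparse.R'
    'stimuli.R'
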