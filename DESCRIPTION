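Package: cellcascades
Title: Cell-Class Annotation by Gene Regulatory Network Structure Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents cellular identities as sets of gene cascades (one- or
    two-gene sets with a distinguished dependent gene), equips each cascade with
    a tropical semiring so that discarding genes is a quotient operation
    equivalent to treating them as exogenous factors, and compares cell classes
    through the asymmetric structural similarity d* between eigen-cascade sets
    learned from pooled expression matrices with a PC-stable skeleton search.
    Includes the full annotation pipeline: marker-panel and factor-analysis
    (KMO/MSA, parallel analysis, quartimin) feature selection, gradient-boosting
    feature importance with grouped stratified cross-validation, k-means cell
    classes with silhouette diagnostics, planet-plot comparisons, and a
    synthetic linear-Gaussian generator with known ground-truth networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    igraph,
    jsonlite,
    yaml,
    xgboost,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
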