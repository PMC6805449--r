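Package: psma
Title: Probabilistic Surfaces of Molecular Activity from Similarity Matrices
Version: 0.1.0
Authors@R: person("PSMA", "Maintainers", email = "psma@example.org",
    role = c("aut", "cre"))
Description: Builds probabilistic surfaces of molecular activity (PSMA) from
    a molecular similarity matrix and an activity table.  Similarities are
    transformed into distances with a convex transform, projected to two
    dimensions with distance-preserving methods (principal coordinates
    analysis, Kruskal non-metric MDS, Sammon mapping, t-SNE), and per-class
    2D Gaussian kernel density maps with Silverman bandwidths are combined
    by Bayes' theorem into a posterior activity surface usable both for
    visualization and as a spatial binary classifier.  Includes linear
    out-of-sample embedding of new molecules, ROC/AUC and Matthews
    correlation evaluation, and a synthetic-data generator with known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
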