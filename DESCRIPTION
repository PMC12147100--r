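Package: scEnsembleTree
Title: Recursive Ensemble Clustering of Single-Cell RNA-Seq Data with
    Explicit Robustness Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-resolution clustering of single-cell RNA-seq count
    matrices by a recursive ensemble strategy. Several base clustering
    methods are run on a pool of cells; cells grouped together by
    strongly similar base clusters are extracted as connected components
    of a similarity graph, scored by the weighted density of the
    component (a robustness value in [0, 1]), filtered by a marker-gene
    characterization rule, and recursed to build a cluster tree in which
    each split must be more robust than its parent. Includes a
    negative-binomial synthetic-data generator with ground-truth labels
    and the standard extrinsic (NMI, ARI) and intrinsic (silhouette,
    neighborhood purity) evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    cluster,
    stats,
    utils,
    graphics,
    methods
Suggests:
    mclust,
    data.table,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
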