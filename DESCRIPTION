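Package: RFsubtypes
Title: Prior-Knowledge-Guided Cancer Subtype Discovery with Parallel
    Random Forests and an Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers refined cancer subtypes from high-dimensional gene
    expression data guided by known subtype labels. Ten independently
    shuffled random forests score genes by Gini (mean decrease in
    impurity) importance against the prior subtype labels; the
    intersection of the ten high-importance gene sets forms a consensus
    feature panel. A symmetric deep autoencoder condenses the panel to a
    two-dimensional core embedding, which k-means++ clusters into
    candidate subtypes, with the cluster number chosen by silhouette
    width against a user-supplied baseline. Includes clustering validity
    metrics (purity, normalized mutual information, silhouette width,
    Davies-Bouldin index, adjusted Rand index), a synthetic expression
    data generator with planted subtype structure, a t-SNE visualisation
    helper, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    patchwork,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
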