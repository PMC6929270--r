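Package: robustclust
Title: Robustness of Clustering Algorithms Across Parameter Settings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how stable a clustering algorithm's output is as its
    tunable settings vary. The central statistic, robustness R = t/(d*r), is
    the proportion of runs in which an ever-co-clustered pair of items stays
    together, averaged over all such pairs, for one algorithm on one dataset
    across a setting sweep. Ships the clustering methods commonly swept on
    gene co-expression data (agglomerative hierarchical with four linkages,
    k-means, quality-threshold clustering, self-organizing maps, paraclique,
    and nearest-neighbor-network clustering), Pearson co-expression graph
    construction with hard thresholding, a parameter-sweep harness, readers
    and writers for cluster-membership and expression files, and a synthetic
    generator of module-structured expression data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
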