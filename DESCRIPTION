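Package: gbda
Title: Benchmarking Graph-Based Data Approximations via Segment-Induced Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct and benchmark graph-based approximations of
    multidimensional point clouds, as used in single-cell trajectory
    inference. An embedded graph is decomposed into maximal non-branching
    segments; the segments induce a clustering of the data cloud, so that
    graph similarity (graph versus graph) and graph quality (graph versus
    data) reduce to standard clustering-comparison and clustering-quality
    scores (adjusted Rand index, adjusted mutual information,
    Fowlkes-Mallows, V-measure; silhouette, Calinski-Harabasz,
    Davies-Bouldin). Two approximators are included: a minimum-spanning-tree
    method over k-means centers and an elastic principal tree grown by
    topological grammar operations, together with a generator of
    ground-truthed tree-shaped synthetic datasets and benchmark drivers for
    node-number scans and stability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
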