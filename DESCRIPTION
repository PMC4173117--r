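Package: dendroheat
Title: Hierarchical Clustering and Cluster-Heatmap JSON Documents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Prepares cluster-heatmap documents from delimited data tables:
    min-max feature scaling, agglomerative hierarchical clustering of rows
    and columns (with an independent naive oracle for verification),
    dendrogram-cut row compression with mean or median aggregation, and
    serialization, parsing and validation of the three-block JSON
    cluster-heatmap document format (data, metadata, column dendrogram).
    Also provides programmatic exploration queries over the dendrogram,
    a deterministic static SVG renderer, grouping of compound identifiers
    by molecular scaffold keys, a command-line front end and synthetic-data
    generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    xml2,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
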