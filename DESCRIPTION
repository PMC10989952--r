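Package: heatcompose
Title: Composable Cluster Heatmaps with Splitting, Annotations and Genomic High-Level Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A layout engine for complex heatmap visualization of matrix-like
    data. Single heatmaps carry exact break-anchored color mapping functions,
    hierarchical clustering with weighted dendrogram reordering, and three
    splitting mechanisms (consensus k-means, categorical combinations, and
    dendrogram cutting). Heatmaps, annotation tracks (simple, points, lines,
    barplots, boxplots, violins, horizon charts, mark labels and linked
    panels, among others) and further heatmaps concatenate horizontally or
    vertically, with row or column correspondence driven by a designated main
    heatmap. Large heatmap bodies can be rasterized by three image-reduction
    strategies. High-level plots include density heatmaps with
    Kolmogorov-Smirnov distance clustering, 3D bar heatmaps, oncoPrints with
    mutual-exclusivity ordering, UpSet plots over element sets or genomic
    region lists, genome-binned signal tracks and anchored signal-enrichment
    matrices. Deterministic SVG output, a YAML plot configuration schema, a
    command-line interface and seeded fixture generators are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    grid,
    utils,
    tools,
    yaml,
    jsonlite,
    png,
    base64enc
Suggests:
    testthat (>= 3.0.0),
    mclust,
    circlize,
    withr
Config/testthat/edition: 3
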