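Package: MSClust
Title: Multi-Level Minimum Span Clustering of Distance Matrices
Version: 0.99.0
Authors@R:
    person(given = "Package", family = "Author",
           role = c("aut", "cre"), email = "author@example.org")
Description: Automatic, hierarchical, multi-level clustering of complex
    networks from a labeled pairwise distance matrix by minimum span
    clustering (MSC): each node links to its nearest neighbour, connected
    components of those links form clusters, clusters are renormalized to
    single nodes (inter-cluster distance = minimum cross-pair distance) and
    the procedure recurses until a desired number of groups is reached.
    Outliers are flagged by a median-based threshold on the shortest-distance
    list at the final two levels. The nested partitions are integrated into
    an MSC tree whose edges carry their clustering level, core/non-core
    status and inter-cluster distance, exportable as edge-list TSV, GraphML
    and Newick. Includes pair-counting Jaccard comparison of partitions, a
    planted-partition synthetic-matrix generator with separation guarantees,
    readers/writers for square and lower-triangular delimited and PHYLIP
    distance formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
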