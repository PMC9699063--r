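test_that("toy hierarchy integrates into the expected 4-edge tree", {
    h <- runMSC(toyT1(), mscParams(m = 10, nLimit = 1))
    tree <- buildMSCTree(h)
    e <- treeEdges(tree)
    expect_equal(nrow(e), 4L)
    expect_equal(sum(e$kind == "core"), 2L)
    expect_equal(sum(e$kind == "member"), 1L)
    l2 <- e[e$level == 2L, ]
    expect_equal(l2$kind, "inter_cluster")
    expect_equal(l2$distance, 10)
    # the level-2 edge joins an element of {A,B,C} with one of {D,E}
    expect_true(l2$source %in% c("A", "B", "C"))
    expect_true(l2$target %in% c("D", "E"))
    g <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                       directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::gsize(g), igraph::gorder(g) - 1L)  # acyclic

    boxes <- clusterBoxes(tree)
    expect_equal(boxes$L1$L1G1, c("A", "B", "C"))
    expect_equal(boxes$L2$L2G1, LETTERS[1:5])
})

test_that("a single 2-node group yields exactly one core edge", {
    v <- matrix(c(0, 7, 7, 0), 2, dimnames = rep(list(c("a", "b")), 2))
    h <- runMSC(DistanceMatrix(v), mscParams(nLimit = 1))
    e <- treeEdges(buildMSCTree(h))
    expect_equal(nrow(e), 1L)
    expect_equal(e$kind, "core")
    expect_equal(e$distance, 7)
})

test_that("runs to one group span n elements with n-1 acyclic edges", {
    cases <- list(
        generatePlanted(plantedSpec(c(10, 10, 10), seed = 21))$dm,
        randomDM(35, seed = 77),
        randomDM(20, seed = 78))
    for (dm in cases) {
        h <- runMSC(dm, mscParams(m = Inf, nLimit = 1))
        expect_equal(groupCounts(h)[nLevels(h)], 1L)
        e <- treeEdges(buildMSCTree(h))
        n <- nElements(dm)
        expect_equal(nrow(e), n - 1L)
        g <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                           directed = FALSE,
                                           vertices = labels(dm))
        expect_true(igraph::is_connected(g))
        expect_equal(igraph::gsize(g), n - 1L)  # connected + n-1 = tree
    }
})

test_that("inter-cluster edge distances equal raw minimum cross distances", {
    dm <- randomDM(30, seed = 91)
    h <- runMSC(dm, mscParams(m = Inf, nLimit = 1))
    tree <- buildMSCTree(h)
    e <- treeEdges(tree)
    raw <- as.matrix(dm)
    memb <- h@membership
    ic <- e[e$kind == "inter_cluster", ]
    expect_gt(nrow(ic), 0L)
    for (k in seq_len(nrow(ic))) {
        l <- ic$level[k]
        ga <- memb[ic$source[k], l - 1L]
        gb <- memb[ic$target[k], l - 1L]
        ea <- rownames(memb)[memb[, l - 1L] == ga]
        eb <- rownames(memb)[memb[, l - 1L] == gb]
        expect_equal(ic$distance[k], min(raw[ea, eb]))
        # and the anchored pair itself realizes that minimum
        expect_equal(raw[ic$source[k], ic$target[k]], min(raw[ea, eb]))
    }
})

test_that("edge-list and GraphML exports carry the same edges", {
    h <- runMSC(randomDM(15, seed = 31), mscParams(m = Inf, nLimit = 1))
    tree <- buildMSCTree(h)
    fe <- withr::local_tempfile(fileext = ".tsv")
    fg <- withr::local_tempfile(fileext = ".graphml")
    exportEdgeList(tree, fe)
    exportGraphML(tree, fg)

    tsv <- read.delim(fe, colClasses = "character")
    doc <- xml2::read_xml(fg)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
    expect_equal(length(edges), nrow(tsv))
    gmlPairs <- sort(paste(xml2::xml_attr(edges, "source"),
                           xml2::xml_attr(edges, "target")))
    expect_equal(gmlPairs, sort(paste(tsv$source, tsv$target)))
    # node count and a colour attribute per edge
    expect_equal(length(xml2::xml_find_all(doc, ".//g:node", ns)),
                 nElements(randomDM(15, seed = 31)))
    cols <- xml2::xml_text(xml2::xml_find_all(
        doc, ".//g:edge/g:data[@key='e_color']", ns))
    expect_true(all(cols %in% c("black", "red", "yellow", "green")))

    # edge list is deterministically ordered
    expect_identical(tsv$level, sort(tsv$level))
})

test_that("Newick export parses and preserves structure", {
    h <- runMSC(toyT1(), mscParams(m = 10, nLimit = 1))
    f <- withr::local_tempfile(fileext = ".nwk")
    exportNewick(h, f)
    tr <- ape::read.tree(f)
    expect_equal(sort(tr$tip.label), LETTERS[1:5])
    expect_true(all(c("L1G1", "L1G2", "L2G1") %in% tr$node.label))
    # A,B,C form a clade, as do D,E
    expect_true(ape::is.monophyletic(tr, c("A", "B", "C")))
    expect_true(ape::is.monophyletic(tr, c("D", "E")))

    v <- matrix(c(0, 7, 7, 0), 2, dimnames = rep(list(c("a", "b")), 2))
    h2 <- runMSC(DistanceMatrix(v), mscParams(nLimit = 1))
    expect_equal(exportNewick(h2), "(a:7,b:7)L1G1;")

    # leaf conservation on random input, including multi-group endings
    dm <- randomDM(18, seed = 13)
    h3 <- runMSC(dm, mscParams(m = 3, nLimit = 4))
    tr3 <- ape::read.tree(text = exportNewick(h3))
    expect_equal(sort(tr3$tip.label), sort(labels(dm)))
})
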