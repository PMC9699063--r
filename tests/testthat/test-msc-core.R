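test_that("shortest-distance list: toy values, ties and the median rule", {
    sdl <- buildSDL(toyT1())
    # C is equidistant (2) from A and B: tie resolves to the smaller index A
    expect_equal(sdl@labels[sdl@nearest], c("B", "A", "A", "E", "D"))
    expect_equal(sdl@nearestDist, c(1, 1, 2, 1, 1))
    expect_equal(sdl@lMed, 1)

    v <- matrix(c(0, 7, 7, 0), 2, dimnames = rep(list(c("a", "b")), 2))
    sdl2 <- buildSDL(DistanceMatrix(v))
    expect_equal(sdl2@nearest, c(2L, 1L))
    expect_equal(sdl2@nearestDist, c(7, 7))
    expect_equal(sdl2@lMed, 7)

    expect_error(buildSDL(DistanceMatrix(matrix(0, 1, 1,
        dimnames = list("a", "a")))), "at least 2")
})

test_that("shortest-distance list matches the brute-force row minimum", {
    dm <- randomDM(50, seed = 101)
    sdl <- buildSDL(dm)
    v <- as.matrix(dm)
    for (i in seq_len(50)) {
        expect_equal(sdl@nearestDist[i], min(v[i, -i]))
        expect_equal(v[i, sdl@nearest[i]], min(v[i, -i]))
    }
})

test_that("outlier rule: threshold m x L_med with the lower median", {
    mk <- function(nd) new("ShortestDistanceList",
        labels = paste0("n", seq_along(nd)),
        nearest = c(seq_along(nd)[-1L], 1L), nearestDist = nd,
        lMed = MSClust:::.lowerMedian(nd))
    expect_equal(detectOutliers(mk(c(1, 1, 2, 1, 50)), m = 3), "n5")
    expect_equal(detectOutliers(mk(rep(2, 6)), m = 1), character(0))
    # even length: lower median of 1,2,3,4 is 2 -> threshold 2 at m = 1
    expect_equal(detectOutliers(mk(c(1, 2, 3, 4)), m = 1), c("n3", "n4"))
    expect_equal(detectOutliers(mk(c(1, 2, 3, 4)), m = Inf), character(0))
    expect_error(detectOutliers(mk(c(1, 2)), m = 0), "positive")
    expect_error(detectOutliers(mk(c(1, 2)), m = -3), "positive")
})

test_that("level clustering: components, core links, outlier singletons", {
    dm <- toyT1()
    sdl <- buildSDL(dm)
    cl <- clusterLevel(dm, sdl, level = 1L)
    expect_equal(groupMembers(cl),
                 list(L1G1 = c("A", "B", "C"), L1G2 = c("D", "E")))
    expect_equal(lapply(cl@coreLinks, function(x) cl@labels[x]),
                 list(c("A", "B"), c("D", "E")))
    expect_equal(cl@labels[cl@memberLinks[3L]], "A")  # C joins via A

    v2 <- matrix(c(0, 7, 7, 0), 2, dimnames = rep(list(c("a", "b")), 2))
    dm2 <- DistanceMatrix(v2)
    cl2 <- clusterLevel(dm2, buildSDL(dm2), 1L)
    expect_equal(nGroups(cl2), 1L)
    expect_equal(cl2@coreLinks[[1L]], c(1L, 2L))

    # declaring C an outlier: nearest links recomputed without it
    cl3 <- clusterLevel(dm, sdl, 1L, outliers = "C")
    expect_equal(groupMembers(cl3),
                 list(L1G1 = c("A", "B"), L1G2 = "C", L1G3 = c("D", "E")))
    expect_equal(cl3@coreLinks[[2L]], integer(0))
    expect_equal(outlierLabels(cl3), "C")
    expect_error(clusterLevel(dm, sdl, 1L, outliers = "Z"), "unknown")
})

test_that("renormalization takes the minimum cross-pair distance", {
    dm <- toyT1()
    cl <- clusterLevel(dm, buildSDL(dm), 1L)
    rn <- renormalize(dm, cl)
    expect_equal(labels(rn), c("L1G1", "L1G2"))
    expect_equal(as.matrix(rn)[1, 2], 10)

    # all-singleton clustering: identity up to relabeling
    sdl <- buildSDL(dm)
    allOut <- clusterLevel(dm, sdl, 1L, outliers = labels(dm))
    rn2 <- renormalize(dm, allOut)
    expect_equal(unname(as.matrix(rn2)), unname(as.matrix(dm)))

    # planted 3 blocks: every off-diagonal of the 3x3 renormalized matrix
    # lies in the between-block interval
    g <- generatePlanted(plantedSpec(c(5, 5, 5),
                                     noiseInterval = c(0, 1),
                                     levelGaps = list(c(5, 6)), seed = 3))
    bl <- g$truth$bottom
    blGroups <- unname(split(seq_along(bl), bl))
    cl3 <- new("LevelClustering", level = 1L, labels = names(bl),
               groups = blGroups,
               coreLinks = lapply(blGroups, function(x) x[1:2]),
               memberLinks = rep(NA_integer_, length(bl)),
               outliers = integer(0), groupIds = paste0("L1G", 1:3),
               nodeGroup = as.integer(factor(bl)))
    rn3 <- renormalize(g$dm, cl3)
    off <- as.matrix(rn3)[upper.tri(matrix(0, 3, 3))]
    expect_true(all(off >= 5 & off <= 6))
})

test_that("full run: toy traces, stopping reasons", {
    h <- runMSC(toyT1(), mscParams(m = 10, nLimit = 1))
    expect_equal(nLevels(h), 2L)
    expect_equal(groupCounts(h), c(2L, 1L))
    expect_equal(stopReason(h), "n_limit")

    v <- matrix(c(0, 5, 5, 0), 2, dimnames = rep(list(c("a", "b")), 2))
    h2 <- runMSC(DistanceMatrix(v), mscParams(nLimit = 1))
    expect_equal(groupCounts(h2), 1L)

    # every node an outlier -> partition cannot change -> fixed point
    v3 <- matrix(1000, 4, 4); diag(v3) <- 0
    v3[1, 2] <- v3[2, 1] <- 1
    v3[3, 4] <- v3[4, 3] <- 100
    dimnames(v3) <- rep(list(letters[1:4]), 2)
    h3 <- runMSC(DistanceMatrix(v3), mscParams(m = 0.5, nLimit = 2))
    expect_equal(stopReason(h3), "fixed_point")
    expect_equal(groupCounts(h3)[nLevels(h3)], 4L)

    h4 <- runMSC(toyT1(), mscParams(m = Inf, nLimit = 1, maxLevels = 1))
    expect_equal(stopReason(h4), "max_levels")
    expect_equal(nLevels(h4), 1L)
})

test_that("planted 4-block matrix: level 1 refines blocks, level 2 small", {
    g <- generatePlanted(plantedSpec(rep(10, 4), noiseInterval = c(0, 1),
                                     levelGaps = list(c(10, 11)),
                                     seed = 17))
    h <- runMSC(g$dm, mscParams(m = Inf, nLimit = 2))
    p1 <- cutPartition(h, 1)
    # every level-1 group lies inside one planted block
    expect_true(all(tapply(g$truth$bottom, p1,
                           function(x) length(unique(x))) == 1L))
    expect_lte(groupCounts(h)[nLevels(h)], 2L)
})

test_that("partitions nest and group counts never increase", {
    for (seed in 1:10) {
        dm <- randomDM(sample(10:40, 1), seed)
        h <- runMSC(dm, mscParams(m = 3, nLimit = 2))
        counts <- groupCounts(h)
        expect_true(all(diff(counts) <= 0))
        if (nLevels(h) > 1) {
            for (l in seq_len(nLevels(h) - 1L)) {
                pl <- cutPartition(h, l)
                pu <- cutPartition(h, l + 1L)
                # coarsening: each lower group maps into one upper group
                expect_true(all(tapply(pu, pl,
                    function(x) length(unique(x))) == 1L))
            }
        }
    }
})

test_that("repeated runs are identical", {
    dm <- randomDM(30, seed = 5)
    h1 <- runMSC(dm, mscParams())
    h2 <- runMSC(dm, mscParams())
    expect_identical(h1@membership, h2@membership)
    expect_identical(h1@stopReason, h2@stopReason)
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeAssignments(h1, f1); writeAssignments(h2, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
})

test_that("hierarchy is invariant under strictly increasing transforms", {
    for (seed in 1:8) {
        dm <- randomDM(25, seed + 200)
        base <- runMSC(dm, mscParams(m = Inf, nLimit = 1))
        for (d in c(0.02, 0.5, 2)) {
            tr <- runMSC(transformDistances(dm, d),
                         mscParams(m = Inf, nLimit = 1))
            expect_identical(tr@membership, base@membership)
        }
        # a non-power strictly increasing map with f(0) = 0
        v <- as.matrix(dm)
        f <- DistanceMatrix(log1p(v) * 3)
        expect_identical(runMSC(f, mscParams(m = Inf, nLimit = 1))@membership,
                         base@membership)
    }
})

test_that("core links are the closest mutual-nearest pair of their group", {
    for (seed in 1:5) {
        dm <- randomDM(40, seed + 50)
        v <- as.matrix(dm)
        sdl <- buildSDL(dm)
        cl <- clusterLevel(dm, sdl, 1L)
        for (gi in seq_len(nGroups(cl))) {
            g <- cl@groups[[gi]]
            if (length(g) < 2L) next
            core <- cl@coreLinks[[gi]]
            # exhaustive search for mutual-nearest pairs inside the group
            mut <- list()
            for (i in g) for (j in g) {
                if (i < j && sdl@nearest[i] == j && sdl@nearest[j] == i)
                    mut[[length(mut) + 1L]] <- c(i, j)
            }
            expect_gte(length(mut), 1L)
            best <- mut[[which.min(vapply(mut,
                function(p) v[p[1L], p[2L]], numeric(1)))]]
            expect_equal(sort(core), best)
            # the core pair is mutual nearest
            expect_equal(sdl@nearest[core[1L]], core[2L])
            expect_equal(sdl@nearest[core[2L]], core[1L])
        }
    }
})
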