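#' Clustering run parameters
#'
#' @param m positive outlier multiplier; a node is an outlier when its
#'   nearest-neighbour distance exceeds `m * L_med` (L_med = median of the
#'   shortest-distance list). `Inf` disables outlier detection.
#' @param nLimit minimum number of groups desired at the final level;
#'   iteration stops at the first level with at most `nLimit` groups.
#' @param maxLevels safety cap on the level count.
#' @return an [MSCParams-class] object.
#' @examples
#' mscParams(m = 3, nLimit = 3)
#' @export
mscParams <- function(m = 3, nLimit = 3, maxLevels = 20) {
    new("MSCParams", m = as.numeric(m), nLimit = as.integer(nLimit),
        maxLevels = as.integer(maxLevels))
}

setMethod("show", "MSCParams", function(object) {
    cat(sprintf("MSCParams: m = %g, nLimit = %d, maxLevels = %d\n",
                object@m, object@nLimit, object@maxLevels))
})

#' Build the shortest-distance list
#'
#' Simplifies the N x N distance matrix to a length-N list: every node's
#' nearest other node and the distance to it, plus the list median L_med.
#' Nearest-neighbour ties are broken toward the smallest node index; the
#' median of an even-length list is the lower of the two middle values.
#'
#' @param dm a [DistanceMatrix-class] with at least 2 elements.
#' @return a [ShortestDistanceList-class].
#' @examples
#' v <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' buildSDL(DistanceMatrix(v))
#' @export
buildSDL <- function(dm) {
    stopifnot(is(dm, "DistanceMatrix"))
    n <- nElements(dm)
    if (n < 2L) stop("need at least 2 elements, got ", n)
    v <- dm@values
    diag(v) <- Inf
    nn <- max.col(-v, ties.method = "first")
    nd <- v[cbind(seq_len(n), nn)]
    new("ShortestDistanceList", labels = labels(dm), nearest = as.integer(nn),
        nearestDist = as.numeric(nd), lMed = .lowerMedian(nd))
}

setMethod("show", "ShortestDistanceList", function(object) {
    cat("ShortestDistanceList of length", length(object@labels),
        sprintf("(L_med = %g)\n", object@lMed))
})

#' @describeIn buildSDL the shortest-distance list as a data.frame with
#'   columns label, nearest, distance.
#' @param sdl a [ShortestDistanceList-class].
#' @export
sdlTable <- function(sdl) {
    stopifnot(is(sdl, "ShortestDistanceList"))
    data.frame(label = sdl@labels, nearest = sdl@labels[sdl@nearest],
               distance = sdl@nearestDist)
}

#' Detect outliers from the shortest-distance list
#'
#' A node is an outlier when its nearest-neighbour distance exceeds
#' `m * L_med`. A single pass: L_med is not recomputed after removal.
#'
#' @param sdl a [ShortestDistanceList-class].
#' @param m positive multiplier; `Inf` flags nothing.
#' @return character vector of outlier node labels.
#' @examples
#' v <- matrix(10, 4, 4); diag(v) <- 0
#' v[1, 2] <- v[2, 1] <- 1; v[3, 4] <- v[4, 3] <- 1
#' dimnames(v) <- rep(list(letters[1:4]), 2)
#' detectOutliers(buildSDL(DistanceMatrix(v)), m = 3)
#' @export
detectOutliers <- function(sdl, m) {
    stopifnot(is(sdl, "ShortestDistanceList"))
    if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
        stop("'m' must be a single positive number")
    if (!is.finite(m)) return(character(0))
    sdl@labels[sdl@nearestDist > m * sdl@lMed]
}

#' Cluster one level by nearest-neighbour links
#'
#' Partitions the non-outlier nodes into the connected components of the
#' undirected graph whose edges join every node to its nearest neighbour
#' (nearest links are recomputed with outliers excluded). Every outlier is
#' its own singleton group. Each multi-node group's core link is its closest
#' internal mutual-nearest pair; every other member carries the non-core
#' nearest link through which it joins the group. Groups are numbered
#' G1, G2, ... by the smallest node index they contain.
#'
#' @param dm the level's [DistanceMatrix-class].
#' @param sdl the [ShortestDistanceList-class] built from `dm` (used for
#'   consistency checking; links are recomputed when outliers are removed).
#' @param level positive integer, the level being clustered.
#' @param outliers character vector of outlier node labels (possibly empty).
#' @return a [LevelClustering-class].
#' @export
clusterLevel <- function(dm, sdl, level, outliers = character(0)) {
    stopifnot(is(dm, "DistanceMatrix"), is(sdl, "ShortestDistanceList"))
    labs <- labels(dm)
    if (!identical(labs, sdl@labels))
        stop("sdl was not built from dm (label mismatch)")
    n <- length(labs)
    outIdx <- match(outliers, labs)
    if (anyNA(outIdx)) stop("unknown outlier label")
    keep <- setdiff(seq_len(n), outIdx)
    nnFull <- rep(NA_integer_, n)
    if (length(keep) >= 2L) {
        if (length(keep) == n) {
            nnFull <- sdl@nearest
        } else {
            sub <- dm@values[keep, keep, drop = FALSE]
            diag(sub) <- Inf
            nnFull[keep] <- keep[max.col(-sub, ties.method = "first")]
        }
        edges <- cbind(keep, nnFull[keep])
    } else {
        edges <- matrix(integer(0), 0L, 2L)
    }
    comp <- .components(n, edges)
    groups <- split(seq_len(n), comp)
    names(groups) <- NULL
    coreLinks <- lapply(groups, function(g) {
        if (length(g) < 2L) return(integer(0))
        mut <- g[nnFull[nnFull[g]] == g & nnFull[g] > g]
        if (!length(mut))  # cannot happen for an NN-link component
            stop("internal error: group without a mutual nearest pair")
        d <- dm@values[cbind(mut, nnFull[mut])]
        i <- mut[order(d, mut)[1L]]
        c(i, nnFull[i])
    })
    new("LevelClustering", level = as.integer(level), labels = labs,
        groups = groups, coreLinks = coreLinks, memberLinks = nnFull,
        outliers = sort(as.integer(outIdx)),
        groupIds = sprintf("L%dG%d", as.integer(level), seq_along(groups)),
        nodeGroup = comp)
}

#' @rdname LevelClustering-class
#' @param x,object a `LevelClustering`
#' @export
setMethod("nGroups", "LevelClustering", function(x) length(x@groups))

#' @rdname LevelClustering-class
#' @export
setMethod("groupIds", "LevelClustering", function(x) x@groupIds)

#' @rdname LevelClustering-class
#' @export
setMethod("groupMembers", "LevelClustering", function(x, ...) {
    out <- lapply(x@groups, function(g) x@labels[g])
    names(out) <- x@groupIds
    out
})

#' @rdname LevelClustering-class
#' @export
setMethod("outlierLabels", "LevelClustering", function(x)
    x@labels[x@outliers])

setMethod("show", "LevelClustering", function(object) {
    cat(sprintf("LevelClustering at level %d: %d nodes in %d groups",
                object@level, length(object@labels), nGroups(object)))
    if (length(object@outliers))
        cat(sprintf(" (%d outliers)", length(object@outliers)))
    cat("\nsizes:", paste(lengths(object@groups), collapse = " "), "\n")
})

#' Renormalize a distance matrix over a clustering
#'
#' Treats every group as a single node of the next level: the G x G output
#' has entry (g, h) equal to the minimum pairwise distance between members
#' of g and members of h, labeled by the group ids.
#'
#' @param dm the level's [DistanceMatrix-class].
#' @param clustering the [LevelClustering-class] of that level.
#' @return a [DistanceMatrix-class] over the groups.
#' @export
renormalize <- function(dm, clustering) {
    stopifnot(is(dm, "DistanceMatrix"), is(clustering, "LevelClustering"))
    if (!identical(labels(dm), clustering@labels))
        stop("clustering does not partition dm's nodes")
    v <- dm@values
    groups <- clustering@groups
    G <- length(groups)
    if (G < 1L) stop("internal error: empty clustering")
    # min over rows of each group, then min over columns of each group
    m1 <- matrix(NA_real_, G, ncol(v))
    for (g in seq_len(G)) m1[g, ] <- .rowsMin(v, groups[[g]])
    tm1 <- t(m1)
    out <- matrix(NA_real_, G, G)
    for (h in seq_len(G)) out[, h] <- .rowsMin(tm1, groups[[h]])
    diag(out) <- 0
    out <- pmin(out, t(out))  # guard exact symmetry
    dimnames(out) <- list(clustering@groupIds, clustering@groupIds)
    new("DistanceMatrix", values = out)
}

# One full clustering pass; outlier detection active at levels >= detectFrom.
.mscPass <- function(dm, params, detectFrom) {
    levels <- list(); mats <- list(); sdls <- list()
    cur <- dm
    reason <- NULL
    repeat {
        lvl <- length(levels) + 1L
        mats[[lvl]] <- cur
        sdl <- buildSDL(cur)
        sdls[[lvl]] <- sdl
        outs <- if (lvl >= detectFrom) detectOutliers(sdl, params@m)
                else character(0)
        cl <- clusterLevel(cur, sdl, lvl, outs)
        levels[[lvl]] <- cl
        G <- nGroups(cl)
        if (G <= params@nLimit) { reason <- "n_limit"; break }
        if (G == nElements(cur)) { reason <- "fixed_point"; break }
        if (lvl >= params@maxLevels) { reason <- "max_levels"; break }
        cur <- renormalize(cur, cl)
    }
    list(levels = levels, mats = mats, sdls = sdls, reason = reason)
}

#' Run multi-level minimum span clustering
#'
#' Iterates the four-step procedure: simplification of the distance matrix
#' to the shortest-distance list, nearest-link clustering, renormalization
#' of clusters to nodes of the next level, and outlier detection with the
#' `m * L_med` threshold at the last two levels. Iteration stops at the
#' first level whose group count is at most `nLimit`, at a fixed point
#' (partition unchanged), or at `maxLevels`.
#'
#' Because the final level is unknown until convergence, outlier detection
#' uses a two-pass strategy: a first pass without detection determines the
#' level count L, then the clustering is re-run with detection enabled from
#' level L-1 onward. If the second pass runs deeper than L, detection stays
#' enabled on the extra levels.
#'
#' @param dm a [DistanceMatrix-class] with at least 2 elements.
#' @param params an [MSCParams-class], see [mscParams()].
#' @return an [MSCHierarchy-class].
#' @examples
#' v <- matrix(10, 4, 4); diag(v) <- 0
#' v[1, 2] <- v[2, 1] <- 1; v[3, 4] <- v[4, 3] <- 1
#' dimnames(v) <- rep(list(letters[1:4]), 2)
#' h <- runMSC(DistanceMatrix(v), mscParams(nLimit = 1))
#' groupCounts(h)
#' @export
runMSC <- function(dm, params = mscParams()) {
    stopifnot(is(dm, "DistanceMatrix"), is(params, "MSCParams"))
    validObject(params)
    if (nElements(dm) < 2L) stop("need at least 2 elements")
    pass1 <- .mscPass(dm, params, detectFrom = .Machine$integer.max)
    if (is.finite(params@m)) {
        detectFrom <- max(1L, length(pass1$levels) - 1L)
        res <- .mscPass(dm, params, detectFrom = detectFrom)
        detection <- seq(detectFrom, length(res$levels))
    } else {
        res <- pass1
        detection <- integer(0)
    }
    L <- length(res$levels)
    n <- nElements(dm)
    memb <- matrix(NA_character_, n, L,
                   dimnames = list(labels(dm), paste0("L", seq_len(L))))
    node <- seq_len(n)  # each element's node index at the current level
    for (l in seq_len(L)) {
        cl <- res$levels[[l]]
        grp <- cl@nodeGroup[node]
        memb[, l] <- cl@groupIds[grp]
        node <- grp
    }
    new("MSCHierarchy", levels = res$levels, levelMatrices = res$mats,
        sdls = res$sdls, membership = memb, params = params,
        stopReason = res$reason, detectionLevels = as.integer(detection))
}

#' @rdname MSCHierarchy-class
#' @param x,object an `MSCHierarchy`
#' @export
setMethod("nLevels", "MSCHierarchy", function(x) length(x@levels))

#' @rdname MSCHierarchy-class
#' @export
setMethod("groupCounts", "MSCHierarchy", function(x)
    vapply(x@levels, nGroups, integer(1)))

#' @rdname MSCHierarchy-class
#' @export
setMethod("stopReason", "MSCHierarchy", function(x) x@stopReason)

#' @rdname MSCHierarchy-class
#' @param level integer level, 1-based
#' @export
setMethod("cutPartition", "MSCHierarchy", function(x, level) {
    level <- as.integer(level)
    if (level < 1L || level > nLevels(x))
        stop("level must be in 1..", nLevels(x))
    stats::setNames(x@membership[, level], rownames(x@membership))
})

#' @rdname MSCHierarchy-class
#' @export
setMethod("membershipTable", "MSCHierarchy", function(x) {
    df <- data.frame(element = rownames(x@membership), x@membership,
                     row.names = NULL, check.names = FALSE)
    for (l in x@detectionLevels) {
        cl <- x@levels[[l]]
        outGids <- cl@groupIds[cl@nodeGroup[cl@outliers]]
        df[[paste0("outlier_L", l)]] <- x@membership[, l] %in% outGids
    }
    df
})

#' @rdname MSCHierarchy-class
#' @param ... unused
#' @export
setMethod("groupMembers", "MSCHierarchy", function(x, level = nLevels(x)) {
    part <- cutPartition(x, level)
    split(names(part), part)[unique(x@membership[, level])]
})

setMethod("show", "MSCHierarchy", function(object) {
    cat(sprintf("MSCHierarchy: %d elements, %d levels (stop: %s)\n",
                nrow(object@membership), nLevels(object),
                object@stopReason))
    cat("group counts:", paste(groupCounts(object), collapse = " "), "\n")
    if (length(object@detectionLevels))
        cat("outlier detection at levels:",
            paste(object@detectionLevels, collapse = " "), "\n")
})

#' Write the cluster-assignment table
#'
#' One row per original element: its label, its group id at every level and
#' an outlier flag for every level at which detection ran.
#'
#' @param hierarchy an [MSCHierarchy-class].
#' @param path output TSV file.
#' @return invisibly, `path`.
#' @export
writeAssignments <- function(hierarchy, path) {
    stopifnot(is(hierarchy, "MSCHierarchy"))
    utils::write.table(membershipTable(hierarchy), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write the per-level run summary
#'
#' JSON report: per level the group count, group sizes, L_med and outlier
#' count, plus the run parameters and stopping reason.
#'
#' @param hierarchy an [MSCHierarchy-class].
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
writeRunSummary <- function(hierarchy, path) {
    stopifnot(is(hierarchy, "MSCHierarchy"))
    p <- hierarchy@params
    levels <- lapply(seq_len(nLevels(hierarchy)), function(l) {
        cl <- hierarchy@levels[[l]]
        list(level = l, n_nodes = length(cl@labels),
             group_count = nGroups(cl),
             group_sizes = lengths(cl@groups),
             l_med = hierarchy@sdls[[l]]@lMed,
             outlier_count = length(cl@outliers),
             outliers = cl@labels[cl@outliers])
    })
    jsonlite::write_json(
        list(params = list(m = p@m, n_limit = p@nLimit,
                           max_levels = p@maxLevels),
             stop_reason = hierarchy@stopReason,
             detection_levels = hierarchy@detectionLevels,
             levels = levels),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
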