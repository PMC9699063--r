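#' @import methods
NULL

#' Labeled symmetric distance matrix
#'
#' The sole data input of minimum span clustering: an N x N matrix of
#' pairwise distances between labeled network elements. Distances may be
#' evolutionary distances (substitutions per site), BLAST E-values (possibly
#' transformed, see [transformDistances()]) or any other non-negative
#' dissimilarity; the triangle inequality is not required.
#'
#' Invariants enforced by the validity method: square numeric matrix, exact
#' symmetry, zero diagonal, finite non-negative off-diagonal entries, unique
#' non-empty labels as dimnames.
#'
#' @slot values numeric matrix with identical row/column dimnames (the labels).
#' @seealso [DistanceMatrix()], [readDistanceMatrix()], [runMSC()]
#' @exportClass DistanceMatrix
setClass("DistanceMatrix", slots = c(values = "matrix"))

setValidity("DistanceMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) != ncol(v)) return("'values' must be square")
    rn <- rownames(v); cn <- colnames(v)
    if (is.null(rn) || is.null(cn)) return("labels (dimnames) are required")
    if (!identical(rn, cn)) return("row and column labels differ")
    if (anyDuplicated(rn)) return("duplicate labels")
    if (any(!nzchar(rn))) return("empty label")
    if (any(diag(v) != 0)) return("diagonal must be zero")
    off <- v[row(v) != col(v)]
    if (length(off) && (any(!is.finite(off)) || any(off < 0)))
        return("off-diagonal distances must be finite and non-negative")
    if (!identical(v, t(v))) return("matrix is not symmetric")
    TRUE
})

#' Shortest-distance list
#'
#' The length-N simplification of the N^2 distance matrix: for every node,
#' its nearest other node and the distance to it, together with the median
#' of those nearest distances (L_med, the reference scale for the
#' m x L_med outlier threshold). Ties for the nearest neighbour are broken
#' toward the smallest node index; the median of an even-length list is the
#' lower of the two middle values.
#'
#' @slot labels character, node labels at this level.
#' @slot nearest integer, index of each node's nearest other node.
#' @slot nearestDist numeric, distance to that neighbour.
#' @slot lMed numeric(1), lower median of `nearestDist`.
#' @seealso [buildSDL()], [detectOutliers()]
#' @exportClass ShortestDistanceList
setClass("ShortestDistanceList",
    slots = c(labels = "character", nearest = "integer",
              nearestDist = "numeric", lMed = "numeric"))

setValidity("ShortestDistanceList", function(object) {
    n <- length(object@labels)
    if (length(object@nearest) != n || length(object@nearestDist) != n)
        return("nearest/nearestDist length must match labels")
    if (length(object@lMed) != 1L) return("lMed must be a scalar")
    if (n && any(object@nearest == seq_len(n)))
        return("a node cannot be its own nearest neighbour")
    if (n && (any(object@nearest < 1L) || any(object@nearest > n)))
        return("nearest index out of range")
    TRUE
})

#' Single-level clustering
#'
#' The partition of one clustering level's nodes into groups: connected
#' components of the undirected graph whose edges join each non-outlier node
#' to its nearest neighbour (recomputed after outlier removal). Each
#' multi-node group carries exactly one core link (its closest, mutual
#' nearest pair); every other member is attached by its (non-core) nearest
#' link. Outliers are singleton groups. Group ids are "L{level}G{n}", with
#' groups numbered by their smallest member index.
#'
#' @slot level integer(1), clustering level (1 = original elements).
#' @slot labels character, node labels at this level.
#' @slot groups list of integer vectors partitioning the node indices.
#' @slot coreLinks list, per group an integer pair (or integer(0) for
#'   singletons): the group's core link.
#' @slot memberLinks integer, each non-outlier node's nearest-neighbour index
#'   (NA for outliers and for a sole non-outlier node).
#' @slot outliers integer, indices of nodes flagged as outliers.
#' @slot groupIds character, "L{level}G{n}" labels.
#' @slot nodeGroup integer, group index of each node.
#' @seealso [clusterLevel()], [runMSC()]
#' @exportClass LevelClustering
setClass("LevelClustering",
    slots = c(level = "integer", labels = "character", groups = "list",
              coreLinks = "list", memberLinks = "integer",
              outliers = "integer", groupIds = "character",
              nodeGroup = "integer"))

setValidity("LevelClustering", function(object) {
    n <- length(object@labels)
    idx <- sort(unlist(object@groups, use.names = FALSE))
    if (!identical(idx, seq_len(n)))
        return("groups must partition the node indices")
    if (length(object@coreLinks) != length(object@groups))
        return("one coreLinks entry per group required")
    if (length(object@groupIds) != length(object@groups))
        return("one group id per group required")
    if (length(object@memberLinks) != n || length(object@nodeGroup) != n)
        return("memberLinks/nodeGroup must have one entry per node")
    sizes <- lengths(object@groups)
    cls <- lengths(object@coreLinks)
    if (any(cls[sizes >= 2L] != 2L))
        return("every multi-node group needs exactly one core link")
    if (any(cls[sizes == 1L] != 0L))
        return("singleton groups cannot have a core link")
    if (length(object@outliers) &&
        any(sizes[object@nodeGroup[object@outliers]] != 1L))
        return("outliers must be singleton groups")
    TRUE
})

#' Run parameters for minimum span clustering
#'
#' @slot m numeric(1), outlier multiplier: nodes whose nearest-neighbour
#'   distance exceeds m x L_med are flagged as outliers. `Inf` disables
#'   outlier detection.
#' @slot nLimit integer(1), minimum number of groups desired at the final
#'   clustering level; iteration stops at the first level with at most this
#'   many groups.
#' @slot maxLevels integer(1), safety cap on the number of levels.
#' @seealso [mscParams()], [runMSC()]
#' @exportClass MSCParams
setClass("MSCParams",
    slots = c(m = "numeric", nLimit = "integer", maxLevels = "integer"))

setValidity("MSCParams", function(object) {
    if (length(object@m) != 1L || is.na(object@m) || object@m <= 0)
        return("'m' must be a single positive number (Inf allowed)")
    if (length(object@nLimit) != 1L || is.na(object@nLimit) ||
        object@nLimit < 1L)
        return("'nLimit' must be a positive integer")
    if (length(object@maxLevels) != 1L || is.na(object@maxLevels) ||
        object@maxLevels < 1L)
        return("'maxLevels' must be a positive integer")
    TRUE
})

#' Multi-level clustering hierarchy
#'
#' The nested sequence of level clusterings produced by [runMSC()], with the
#' renormalized distance matrix and shortest-distance list that produced each
#' level, a membership table tracing every original element to its group id
#' at every level, and the reason iteration stopped ("n_limit",
#' "fixed_point" or "max_levels").
#'
#' @slot levels list of [LevelClustering-class] objects, level 1 upward.
#' @slot levelMatrices list of [DistanceMatrix-class]; element l is the input
#'   to level l (element 1 is the original matrix).
#' @slot sdls list of [ShortestDistanceList-class], one per level.
#' @slot membership character matrix, elements x levels, of group ids.
#' @slot params [MSCParams-class] used for the run.
#' @slot stopReason character(1).
#' @slot detectionLevels integer, levels at which outlier detection ran.
#' @seealso [runMSC()], [cutPartition()], [buildMSCTree()]
#' @exportClass MSCHierarchy
setClass("MSCHierarchy",
    slots = c(levels = "list", levelMatrices = "list", sdls = "list",
              membership = "matrix", params = "MSCParams",
              stopReason = "character", detectionLevels = "integer"))

setValidity("MSCHierarchy", function(object) {
    L <- length(object@levels)
    if (L < 1L) return("at least one level required")
    if (length(object@levelMatrices) != L || length(object@sdls) != L)
        return("one input matrix and one SDL per level required")
    if (ncol(object@membership) != L)
        return("membership must have one column per level")
    counts <- vapply(object@levels, function(x) length(x@groups), integer(1))
    if (any(diff(counts) > 0L))
        return("group counts must be non-increasing with level")
    TRUE
})

#' Integrated multi-level MSC tree
#'
#' A single graph over the original elements combining all clustering
#' levels. Level-1 edges are the nearest links that formed each group (the
#' closest pair flagged "core", the rest "member"); for every level >= 2
#' merge, "inter_cluster" edges connect the merged subgroups, each realized
#' between the specific element pair achieving the minimum cross-group
#' distance and annotated with that distance. If the run ends in a single
#' group the undirected edge set is a spanning tree (n - 1 edges, acyclic).
#'
#' @slot nodes data.frame: element label plus its group id at every level.
#' @slot edges data.frame with columns source, target, level, kind
#'   (core/member/inter_cluster), distance.
#' @slot clusterBoxes list, per level a named list mapping group id to the
#'   member element labels.
#' @seealso [buildMSCTree()], [exportEdgeList()], [exportGraphML()]
#' @exportClass MSCTree
setClass("MSCTree",
    slots = c(nodes = "data.frame", edges = "data.frame",
              clusterBoxes = "list"))

setValidity("MSCTree", function(object) {
    need <- c("source", "target", "level", "kind", "distance")
    if (!all(need %in% names(object@edges)))
        return("edges must have source, target, level, kind, distance")
    if (nrow(object@edges)) {
        if (any(!object@edges$kind %in% c("core", "member", "inter_cluster")))
            return("invalid edge kind")
        if (any(object@edges$distance < 0))
            return("edge distances must be non-negative")
    }
    TRUE
})
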