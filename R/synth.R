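# Planted-partition generator: labeled distance matrices with known
# hierarchical block structure and optional planted outliers, so every
# clustering stage can be verified against ground truth without external
# data.

#' Specify a planted hierarchical distance structure
#'
#' Describes a synthetic distance matrix with bottom-level blocks nested
#' into super-blocks of arbitrary depth. Distances between two elements are
#' drawn uniformly from the interval dictated by the height of the pair's
#' lowest common super-block: `noiseInterval` within a bottom block,
#' `levelGaps[[h]]` for pairs first joined at height h (h = 1 are sibling
#' blocks inside the same super-block; the largest h spans the whole
#' system). Optional outlier elements sit at distance at least
#' `outlierScale * max(levelGaps[[H]])` from everything, so the m x L_med
#' rule provably flags them.
#'
#' Intervals are drawn uniform (not Gaussian) so that separation - every
#' within-level distance strictly below every next-coarser distance - can be
#' made exact, which turns cluster recovery into a provable property: when
#' separation holds, nearest-neighbour links can never leave a block, so
#' minimum span clustering recovers the planted partition exactly.
#'
#' @param blockSizes integer vector, size of each bottom-level block.
#' @param hierarchy nested list grouping bottom-block indices into
#'   super-blocks, e.g. `list(list(1, 2), list(3, 4))`; `NULL` (default)
#'   makes all blocks siblings at height 1. Every bottom block must appear
#'   exactly once.
#' @param noiseInterval length-2 numeric, within-block distance interval.
#' @param levelGaps list of length-2 intervals, one per height.
#' @param nOutliers number of planted outlier elements.
#' @param outlierScale multiple of the top gap at which outliers sit.
#' @param seed integer seed making the matrix reproducible.
#' @param separation logical; if TRUE (default) the intervals must be
#'   strictly ordered (max of each level below min of the next), which
#'   guarantees exact recovery. Disable only for adversarial tests.
#' @return a validated specification (class `PlantedSpec`).
#' @seealso [generatePlanted()]
#' @export
plantedSpec <- function(blockSizes, hierarchy = NULL,
                        noiseInterval = c(0, 1),
                        levelGaps = list(c(10, 11)),
                        nOutliers = 0L, outlierScale = 100,
                        seed = 1L, separation = TRUE) {
    blockSizes <- as.integer(blockSizes)
    if (!length(blockSizes) || any(blockSizes < 1L))
        stop("'blockSizes' must be positive integers")
    B <- length(blockSizes)
    if (is.null(hierarchy)) hierarchy <- as.list(seq_len(B))
    leaves <- unlist(hierarchy)
    if (!setequal(leaves, seq_len(B)) || length(leaves) != B)
        stop("'hierarchy' must contain every bottom block exactly once")
    H <- .treeHeight(hierarchy)
    if (length(levelGaps) < H)
        stop("'levelGaps' needs one interval per height (", H, " required)")
    ivs <- c(list(noiseInterval), levelGaps[seq_len(H)])
    for (iv in ivs)
        if (length(iv) != 2L || any(iv < 0) || iv[2L] < iv[1L])
            stop("intervals must be ordered non-negative pairs")
    if (separation) {
        for (k in seq_len(length(ivs) - 1L))
            if (ivs[[k]][2L] >= ivs[[k + 1L]][1L])
                stop("separation violated: interval at height ", k - 1L,
                     " overlaps height ", k)
    }
    if (nOutliers > 0 && outlierScale <= 1)
        stop("'outlierScale' must exceed 1")
    structure(list(blockSizes = blockSizes, hierarchy = hierarchy,
                   noiseInterval = as.numeric(noiseInterval),
                   levelGaps = lapply(levelGaps[seq_len(H)], as.numeric),
                   nOutliers = as.integer(nOutliers),
                   outlierScale = as.numeric(outlierScale),
                   seed = as.integer(seed), height = H,
                   separation = isTRUE(separation)),
              class = "PlantedSpec")
}

# height of a nested-list block tree: a bare block index has height 0,
# a node is 1 + max height of its children
.treeHeight <- function(node) {
    if (!is.list(node)) return(0L)
    1L + max(vapply(node, .treeHeight, integer(1)), 0L)
}

# For every bottom block, the id of its enclosing super-block at each
# height 1..H (the lowest ancestor node of height >= h), plus the pairwise
# merge height of every two blocks.
.blockAncestry <- function(hierarchy, B, H) {
    anc <- matrix(seq_len(B), B, H)  # default: block is its own ancestor
    nodeId <- 0L
    walk <- function(node) {
        if (!is.list(node)) return(list(leaves = node, height = 0L))
        kids <- lapply(node, walk)
        h <- 1L + max(vapply(kids, `[[`, integer(1), "height"))
        leaves <- unlist(lapply(kids, `[[`, "leaves"))
        nodeId <<- nodeId + 1L
        # this node is the ancestor at its own height for all its leaves,
        # and (being the lowest such) also at heights down to child+1
        for (k in kids) {
            for (hh in seq(k$height + 1L, h))
                anc[k$leaves, hh] <<- B + nodeId
        }
        list(leaves = leaves, height = h)
    }
    root <- walk(hierarchy)
    # pairwise merge height: smallest h at which two blocks share an ancestor
    mh <- matrix(0L, B, B)
    for (a in seq_len(B)) for (b in seq_len(B)) {
        if (a == b) next
        shared <- which(anc[a, ] == anc[b, ])
        mh[a, b] <- if (length(shared)) min(shared) else H
    }
    list(anc = anc, mergeHeight = mh)
}

#' Generate a planted-partition distance matrix
#'
#' Draws the symmetric matrix described by a [plantedSpec()]: zero diagonal,
#' each off-diagonal distance uniform in the interval dictated by the pair's
#' merge height, outlier distances uniform in
#' `[S, 1.05 S]` with `S = outlierScale * max(levelGaps[[H]])`. Reproducible
#' from the spec's seed (the global RNG state is left untouched).
#'
#' @param spec a `PlantedSpec` from [plantedSpec()].
#' @return a list with elements `dm` (the [DistanceMatrix-class]), `truth`
#'   (list of ground-truth partitions: `$bottom` plus one per height, each a
#'   named vector over all elements with outliers as singletons) and
#'   `outliers` (character vector of planted outlier labels).
#' @examples
#' g <- generatePlanted(plantedSpec(c(5, 5, 5), seed = 7))
#' nElements(g$dm)
#' table(g$truth$bottom)
#' @export
generatePlanted <- function(spec) {
    stopifnot(inherits(spec, "PlantedSpec"))
    sizes <- spec$blockSizes
    B <- length(sizes)
    H <- spec$height
    nCore <- sum(sizes)
    nOut <- spec$nOutliers
    n <- nCore + nOut
    bid <- rep(seq_len(B), sizes)
    labs <- c(sprintf("B%d_%d", bid, sequence(sizes)),
              if (nOut) sprintf("OUT%d", seq_len(nOut)))
    anc <- .blockAncestry(spec$hierarchy, B, H)
    lows <- c(spec$noiseInterval[1L],
              vapply(spec$levelGaps, `[`, numeric(1), 1L))
    highs <- c(spec$noiseInterval[2L],
               vapply(spec$levelGaps, `[`, numeric(1), 2L))
    # per-pair interval index: merge height + 1 (0 -> within block)
    hIdx <- anc$mergeHeight[bid, bid, drop = FALSE] + 1L
    lowM <- matrix(lows[hIdx], nCore, nCore)
    highM <- matrix(highs[hIdx], nCore, nCore)
    S <- spec$outlierScale * max(highs)
    if (nOut) {
        lowM <- rbind(cbind(lowM, matrix(S, nCore, nOut)),
                      matrix(S, nOut, n))
        highM <- rbind(cbind(highM, matrix(1.05 * S, nCore, nOut)),
                       matrix(1.05 * S, nOut, n))
    }
    v <- .withSeed(spec$seed, {
        u <- matrix(0, n, n)
        ut <- upper.tri(u)
        u[ut] <- lowM[ut] + stats::runif(sum(ut)) * (highM[ut] - lowM[ut])
        u + t(u)
    })
    dimnames(v) <- list(labs, labs)
    dm <- new("DistanceMatrix", values = v)
    outLabs <- if (nOut) labs[(nCore + 1L):n] else character(0)
    truth <- list(bottom = stats::setNames(
        c(sprintf("block%d", bid), outLabs), labs))
    for (h in seq_len(H)) {
        gid <- c(sprintf("super%d", anc$anc[bid, h]), outLabs)
        truth[[paste0("height", h)]] <- stats::setNames(gid, labs)
    }
    list(dm = dm, truth = truth, outliers = outLabs)
}

#' @describeIn generatePlanted write the matrix (any supported dialect) and
#'   the ground-truth assignment TSV next to it.
#' @param prefix output path prefix; writes `<prefix>.dist.tsv` and
#'   `<prefix>.truth.tsv`.
#' @param format matrix dialect for [writeDistanceMatrix()].
#' @export
writePlanted <- function(spec, prefix, format = "square_delim") {
    g <- generatePlanted(spec)
    writeDistanceMatrix(g$dm, paste0(prefix, ".dist.tsv"), format)
    truthDf <- data.frame(element = names(g$truth$bottom),
                          do.call(cbind, g$truth), check.names = FALSE,
                          row.names = NULL)
    utils::write.table(truthDf, paste0(prefix, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(g)
}
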