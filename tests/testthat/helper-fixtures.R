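# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no data files.

# 5-node toy: A,B,C form a tight cluster (core pair A-B, C attached via A),
# D,E a second cluster; all cross-cluster distances are 10.
toyT1 <- function() {
    v <- matrix(10, 5, 5)
    diag(v) <- 0
    v[1, 2] <- v[2, 1] <- 1
    v[1, 3] <- v[3, 1] <- 2
    v[2, 3] <- v[3, 2] <- 2
    v[4, 5] <- v[5, 4] <- 1
    dimnames(v) <- rep(list(LETTERS[1:5]), 2)
    DistanceMatrix(v)
}

# random symmetric matrix with U(0,1) off-diagonal distances
randomDM <- function(n, seed) {
    set.seed(seed)
    v <- matrix(0, n, n)
    ut <- upper.tri(v)
    v[ut] <- runif(sum(ut))
    v <- v + t(v)
    labs <- sprintf("e%03d", seq_len(n))
    dimnames(v) <- list(labs, labs)
    DistanceMatrix(v)
}

# Independent oracle for level-1 groups: brute-force nearest neighbour per
# row (apply/which.min) and connected components via igraph.
nnComponentsOracle <- function(dm) {
    v <- as.matrix(dm)
    diag(v) <- Inf
    nn <- apply(v, 1L, which.min)  # which.min ties -> lowest index
    g <- igraph::graph_from_edgelist(cbind(seq_len(nrow(v)), nn),
                                     directed = FALSE)
    comp <- igraph::components(g)$membership
    stats::setNames(paste0("c", comp), labels(dm))
}

# partitions as named vectors -> canonical form for equality checks
canonicalPartition <- function(p) {
    groups <- lapply(split(names(p), p), sort)
    unname(groups[order(vapply(groups, `[`, character(1), 1L))])
}

samePartition <- function(p, q) {
    identical(canonicalPartition(p), canonicalPartition(q))
}

# all set partitions of n elements as restricted-growth assignment vectors
allPartitions <- function(n) {
    res <- list()
    rec <- function(prefix, maxg) {
        if (length(prefix) == n) {
            res[[length(res) + 1L]] <<- prefix
            return(invisible(NULL))
        }
        for (g in seq_len(maxg + 1L)) rec(c(prefix, g), max(maxg, g))
    }
    rec(integer(0), 0L)
    lapply(res, function(a) stats::setNames(paste0("g", a),
                                            letters[seq_len(n)]))
}

# exhaustive pair-set Jaccard oracle
pairSet <- function(p) {
    labs <- sort(names(p))
    out <- character(0)
    for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
        if (p[[labs[i]]] == p[[labs[j]]])
            out <- c(out, paste(labs[j], labs[i], sep = "|"))
    }
    out
}

jaccardOracle <- function(p, q) {
    sp <- pairSet(p)
    sq <- pairSet(q)
    if (!length(sp) && !length(sq)) return(1)
    length(intersect(sp, sq)) / length(union(sp, sq))
}

# uniformly random partition assignment (not uniform over partitions; fine
# for property checks)
randPartition <- function(n, k = sample(seq_len(n), 1L)) {
    stats::setNames(paste0("g", sample(seq_len(k), n, replace = TRUE)),
                    letters[seq_len(n)])
}
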