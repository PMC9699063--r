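# Internal helpers shared across the clustering code.

# Connected components of an undirected graph on nodes 1..n given an
# edge matrix (2 columns of node indices). Components are numbered by the
# smallest node index they contain (1 = component of the smallest node).
.components <- function(n, edges) {
    parent <- seq_len(n)
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]  # path halving
            i <- parent[i]
        }
        i
    }
    if (length(edges)) {
        for (k in seq_len(nrow(edges))) {
            a <- findRoot(edges[k, 1L])
            b <- findRoot(edges[k, 2L])
            if (a != b) parent[max(a, b)] <- min(a, b)
        }
    }
    root <- vapply(seq_len(n), findRoot, integer(1))
    match(root, unique(root))
}

# Lower median: for even-length lists the lower of the two middle values.
.lowerMedian <- function(x) {
    n <- length(x)
    if (!n) stop("empty vector")
    sort(x)[floor((n + 1) / 2)]
}

# Parallel minimum over the rows of v indexed by idx (a length->=1 vector):
# returns a vector of per-column minima.
.rowsMin <- function(v, idx) {
    if (length(idx) == 1L) v[idx, ]
    else do.call(pmin, lapply(idx, function(i) v[i, ]))
}

# Save/restore the global RNG state around seeded generation.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}
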