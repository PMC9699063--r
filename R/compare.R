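# Partitions are represented as named vectors: names are the element
# labels (the universe), values are arbitrary group identifiers.

.checkPartition <- function(p, what = "partition") {
    if (is.null(names(p)) || any(!nzchar(names(p))))
        stop(what, " must be a named vector (names = element labels)")
    if (anyDuplicated(names(p)))
        stop(what, " has duplicate element labels")
    if (anyNA(p)) stop(what, " has missing group assignments")
    invisible(p)
}

#' Pair-counting Jaccard similarity of two partitions
#'
#' The standard pair-counting Jaccard index for comparing clusterings:
#' with S_p the set of unordered element pairs co-clustered in p, the
#' similarity is |S_p intersect S_q| / |S_p union S_q|. It is 1 exactly when
#' the two partitions are identical (group labels are irrelevant) and 0 when
#' no co-clustered pair is shared. Two all-singleton partitions (both pair
#' sets empty) compare as 1.
#'
#' @param p,q partitions over the same universe: named vectors mapping
#'   element label to group id (see [cutPartition()]).
#' @return a number in [0, 1].
#' @examples
#' p <- c(A = "g1", B = "g1", C = "g1")
#' q <- c(A = "x", B = "x", C = "y")
#' jaccardPairs(p, q)  # pairs {AB,AC,BC} vs {AB} -> 1/3
#' @export
jaccardPairs <- function(p, q) {
    .checkPartition(p, "p"); .checkPartition(q, "q")
    if (length(p) != length(q) || !setequal(names(p), names(q)))
        stop("partitions are over different universes")
    if (length(p) < 2L) stop("need at least 2 elements")
    q <- q[names(p)]
    tab <- table(as.character(p), as.character(q))
    inter <- sum(choose(tab, 2))
    sp <- sum(choose(rowSums(tab), 2))
    sq <- sum(choose(colSums(tab), 2))
    union <- sp + sq - inter
    if (union == 0) 1 else inter / union
}

#' Compare clustering runs across distance transforms
#'
#' Runs [runMSC()] on `transformDistances(dm, d)` for every exponent in
#' `exponents` and tabulates the pair-counting Jaccard similarity between
#' every pair of runs at every level present in both. Minimum span
#' clustering depends on distances only through comparisons and minima, so
#' the link structure is invariant under any strictly increasing transform;
#' the absolute m x L_med outlier threshold is not, which is why the default
#' parameters here disable outlier detection (`m = Inf`). See the vignette.
#'
#' @param dm a [DistanceMatrix-class].
#' @param params an [MSCParams-class]; default disables outlier detection.
#' @param exponents positive exponents for the E^d family.
#' @return a data.frame with columns level, d1, d2, jaccard.
#' @examples
#' v <- matrix(10, 4, 4); diag(v) <- 0
#' v[1, 2] <- v[2, 1] <- 1; v[3, 4] <- v[4, 3] <- 2
#' dimnames(v) <- rep(list(letters[1:4]), 2)
#' compareRuns(DistanceMatrix(v), exponents = c(1, 0.02))
#' @export
compareRuns <- function(dm, params = mscParams(m = Inf, nLimit = 1),
                        exponents = c(1, 0.02)) {
    stopifnot(is(dm, "DistanceMatrix"))
    if (!length(exponents)) stop("'exponents' must be non-empty")
    runs <- lapply(exponents, function(d)
        runMSC(transformDistances(dm, d), params))
    out <- list()
    for (i in seq_along(runs)) for (j in seq_along(runs)) {
        if (j <= i) next
        common <- seq_len(min(nLevels(runs[[i]]), nLevels(runs[[j]])))
        out[[length(out) + 1L]] <- data.frame(
            level = common, d1 = exponents[i], d2 = exponents[j],
            jaccard = vapply(common, function(l)
                jaccardPairs(cutPartition(runs[[i]], l),
                             cutPartition(runs[[j]], l)), numeric(1)))
    }
    if (!length(out))
        return(data.frame(level = seq_len(nLevels(runs[[1L]])),
                          d1 = exponents[1L], d2 = exponents[1L],
                          jaccard = 1))
    do.call(rbind, out)
}

#' Write a partition-comparison report
#'
#' @param comparison data.frame from [compareRuns()] (or any data.frame of
#'   per-level Jaccard values).
#' @param path output file; `.json` extension selects JSON, anything else
#'   TSV.
#' @return invisibly, `path`.
#' @export
writeComparison <- function(comparison, path) {
    if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::write_json(comparison, path, auto_unbox = FALSE,
                             digits = NA, dataframe = "rows", pretty = TRUE)
    else
        utils::write.table(comparison, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(path)
}

#' Read an externally produced assignment table
#'
#' Reads a delimited table with an element-label column and a group column
#' (by default the first two columns) into a partition vector comparable
#' with [jaccardPairs()].
#'
#' @param path TSV/CSV file with a header row.
#' @param elementCol,groupCol column names or indices.
#' @return named character vector (element -> group).
#' @export
readAssignments <- function(path, elementCol = 1L, groupCol = 2L) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .sniffSep(readLines(path, n = 1L))
    if (nchar(sep) > 1L) sep <- ""  # read.table: "" = any whitespace
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "character")
    .checkPartition(stats::setNames(df[[groupCol]], df[[elementCol]]),
                    basename(path))
}
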