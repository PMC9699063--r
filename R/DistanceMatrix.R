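#' Construct a labeled distance matrix
#'
#' Validates and (by default) symmetrizes a square numeric matrix of
#' pairwise distances. Mild asymmetries, as produced e.g. by all-vs-all
#' BLAST E-values, are averaged: entries with
#' `|a_ij - a_ji| <= asymTol * max(|a_ij|, |a_ji|, 1)` are replaced by their
#' mean; larger asymmetries are an error. The diagonal is forced to zero.
#' Zero off-diagonal distances (identical sequences) are permitted.
#'
#' @param values square numeric matrix.
#' @param labels character vector of unique element labels; defaults to the
#'   rownames of `values`.
#' @param symmetrize logical; average small asymmetries (default TRUE).
#' @param asymTol relative asymmetry tolerance (default 1e-6).
#' @return a [DistanceMatrix-class] object.
#' @examples
#' v <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' dm <- DistanceMatrix(v)
#' nElements(dm)
#' @export
DistanceMatrix <- function(values, labels = NULL, symmetrize = TRUE,
                           asymTol = 1e-6) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (nrow(values) != ncol(values))
        stop("'values' must be square, got ", nrow(values), " x ",
             ncol(values))
    if (is.null(labels)) labels <- rownames(values)
    if (is.null(labels))
        stop("labels are required (argument or rownames)")
    labels <- as.character(labels)
    if (length(labels) != nrow(values))
        stop("length(labels) must equal the matrix dimension")
    if (anyDuplicated(labels))
        stop("duplicate labels: ",
             paste(unique(labels[duplicated(labels)]), collapse = ", "))
    dimnames(values) <- list(labels, labels)
    if (symmetrize && !identical(values, t(values))) {
        tv <- t(values)
        gap <- abs(values - tv)
        scale <- pmax(abs(values), abs(tv), 1)
        bad <- which(gap > asymTol * scale, arr.ind = TRUE)
        if (nrow(bad))
            stop("asymmetry beyond tolerance at [",
                 labels[bad[1L, 1L]], ", ", labels[bad[1L, 2L]], "]: ",
                 values[bad[1L, , drop = FALSE]], " vs ",
                 tv[bad[1L, , drop = FALSE]])
        values <- (values + tv) / 2
    }
    diag(values) <- 0
    new("DistanceMatrix", values = values)
}

#' @rdname DistanceMatrix
#' @export
setMethod("nElements", "DistanceMatrix", function(x) nrow(x@values))

#' @describeIn DistanceMatrix element labels
#' @export
setMethod("labels", "DistanceMatrix", function(object, ...)
    rownames(object@values))

#' @describeIn DistanceMatrix the underlying numeric matrix
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' @describeIn DistanceMatrix matrix dimension
#' @export
setMethod("dim", "DistanceMatrix", function(x) dim(x@values))

setMethod("show", "DistanceMatrix", function(object) {
    n <- nElements(object)
    cat("DistanceMatrix with", n, "elements\n")
    lab <- labels(object)
    shown <- paste(utils::head(lab, 6L), collapse = ", ")
    if (n > 6L) shown <- paste0(shown, ", ...")
    cat("labels:", shown, "\n")
    off <- object@values[row(object@values) != col(object@values)]
    if (length(off))
        cat(sprintf("distance range: [%g, %g]\n", min(off), max(off)))
})

#' Power transform of a distance matrix
#'
#' Replaces every off-diagonal distance x by x^d. With distances taken as
#' BLAST E-values this is the E^d family (d = 1 or a small exponent such as
#' 0.02 that compresses the enormous dynamic range of E-values). The
#' transform is strictly increasing on positive values for every d > 0, so
#' it preserves the order of any two distinct positive distances; minimum
#' span clustering depends on distances only through comparisons and minima
#' and is therefore invariant under it (see the package vignette for the one
#' caveat, the absolute m x L_med outlier threshold).
#'
#' @param dm a [DistanceMatrix-class].
#' @param d positive exponent.
#' @return a new [DistanceMatrix-class] with transformed distances.
#' @examples
#' v <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' as.matrix(transformDistances(DistanceMatrix(v), 0.5))
#' @export
transformDistances <- function(dm, d) {
    stopifnot(is(dm, "DistanceMatrix"))
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0)
        stop("'d' must be a single positive number")
    v <- dm@values ^ d
    diag(v) <- 0
    new("DistanceMatrix", values = v)
}
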