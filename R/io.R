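#' Read a labeled distance matrix
#'
#' Reads a pairwise distance matrix from one of three plain-text dialects
#' and returns a validated [DistanceMatrix-class]. Asymmetric input within a
#' relative tolerance of 1e-6 is averaged; larger asymmetry is an error.
#' Missing entries are not supported: minimum span clustering needs every
#' pairwise distance.
#'
#' Supported formats:
#' \describe{
#'   \item{`square_delim`}{TSV or CSV; first row a header of labels
#'     (optionally preceded by an empty corner cell), each following row a
#'     label plus N distances.}
#'   \item{`lower_triangular_delim`}{row i holds a label plus the i-1
#'     distances to the previous rows (a trailing zero diagonal entry is
#'     tolerated).}
#'   \item{`phylip_dist`}{standard PHYLIP distance matrix: a count line,
#'     then one label plus a full row of N distances per taxon (rows may
#'     wrap; labels must not contain whitespace).}
#' }
#'
#' @param path file to read.
#' @param format one of `"square_delim"`, `"lower_triangular_delim"`,
#'   `"phylip_dist"`.
#' @param asymTol relative asymmetry tolerance passed to [DistanceMatrix()].
#' @return a [DistanceMatrix-class].
#' @seealso [writeDistanceMatrix()]
#' @export
readDistanceMatrix <- function(path,
                               format = c("square_delim",
                                          "lower_triangular_delim",
                                          "phylip_dist"),
                               asymTol = 1e-6) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(raw))
    lines <- raw[keep]
    lineNo <- which(keep)
    if (!length(lines)) stop("empty file: ", path)
    switch(format,
        square_delim = .readSquareDelim(lines, lineNo, asymTol),
        lower_triangular_delim = .readLowerTri(lines, lineNo),
        phylip_dist = .readPhylipDist(lines, lineNo))
}

.sniffSep <- function(line) {
    if (grepl("\t", line, fixed = TRUE)) "\t"
    else if (grepl(",", line, fixed = TRUE)) ","
    else "[[:space:]]+"
}

.parseCell <- function(s, row, col) {
    x <- suppressWarnings(as.numeric(s))
    if (is.na(x))
        stop("non-numeric or missing cell at row ", row, ", column ", col,
             ": '", s, "'")
    x
}

.readSquareDelim <- function(lines, lineNo, asymTol) {
    sep <- .sniffSep(lines[1L])
    header <- trimws(strsplit(lines[1L], sep)[[1L]])
    body <- lines[-1L]
    bodyNo <- lineNo[-1L]
    n <- length(body)
    if (n < 1L) stop("no data rows after header")
    # header may or may not carry a corner cell above the label column
    if (length(header) == n + 1L) header <- header[-1L]
    header <- header[nzchar(header)]
    if (length(header) != n)
        stop("dimension mismatch: header names ", length(header),
             " elements but file has ", n, " data rows")
    v <- matrix(NA_real_, n, n)
    labs <- character(n)
    for (i in seq_len(n)) {
        f <- trimws(strsplit(body[i], sep)[[1L]])
        f <- f[nzchar(f)]
        if (length(f) != n + 1L)
            stop("dimension mismatch at line ", bodyNo[i], " ('", f[1L],
                 "'): expected ", n + 1L, " fields, found ", length(f))
        labs[i] <- f[1L]
        v[i, ] <- vapply(seq_len(n),
                         function(j) .parseCell(f[j + 1L], bodyNo[i], j),
                         numeric(1))
    }
    if (!identical(labs, header))
        stop("row labels disagree with header labels")
    DistanceMatrix(v, labels = labs, asymTol = asymTol)
}

.readLowerTri <- function(lines, lineNo) {
    n <- length(lines)
    v <- matrix(0, n, n)
    labs <- character(n)
    for (i in seq_len(n)) {
        f <- trimws(strsplit(lines[i], "[,\t]|[[:space:]]+")[[1L]])
        f <- f[nzchar(f)]
        labs[i] <- f[1L]
        vals <- f[-1L]
        if (length(vals) == i) {  # diagonal included: must be zero
            d <- .parseCell(vals[i], lineNo[i], i)
            if (d != 0)
                stop("non-zero diagonal at line ", lineNo[i], ": ", d)
            vals <- vals[-i]
        }
        if (length(vals) != i - 1L)
            stop("dimension mismatch at line ", lineNo[i], " ('", labs[i],
                 "'): expected ", i - 1L, " distances, found ", length(vals))
        if (i > 1L)
            v[i, seq_len(i - 1L)] <-
                vapply(seq_len(i - 1L),
                       function(j) .parseCell(vals[j], lineNo[i], j),
                       numeric(1))
    }
    v <- v + t(v)
    DistanceMatrix(v, labels = labs, symmetrize = FALSE)
}

.readPhylipDist <- function(lines, lineNo) {
    n <- suppressWarnings(as.integer(trimws(lines[1L])))
    if (is.na(n) || n < 1L)
        stop("invalid taxon count on line ", lineNo[1L], ": '", lines[1L],
             "'")
    tokens <- unlist(strsplit(trimws(lines[-1L]), "[[:space:]]+"),
                     use.names = FALSE)
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) != n * (n + 1L))
        stop("dimension mismatch: expected ", n, " rows of a label plus ",
             n, " distances (", n * (n + 1L), " tokens), found ",
             length(tokens))
    v <- matrix(NA_real_, n, n)
    labs <- character(n)
    for (i in seq_len(n)) {
        at <- (i - 1L) * (n + 1L)
        labs[i] <- tokens[at + 1L]
        v[i, ] <- vapply(seq_len(n),
                         function(j) .parseCell(tokens[at + 1L + j], i, j),
                         numeric(1))
    }
    DistanceMatrix(v, labels = labs)
}

#' Write a distance matrix
#'
#' Inverse of [readDistanceMatrix()]; values are written with full
#' precision ("%.17g") so that a write/read round trip reproduces the matrix
#' exactly.
#'
#' @param dm a [DistanceMatrix-class].
#' @param path output file.
#' @param format output dialect, see [readDistanceMatrix()].
#' @return invisibly, `path`.
#' @export
writeDistanceMatrix <- function(dm, path,
                                format = c("square_delim",
                                           "lower_triangular_delim",
                                           "phylip_dist")) {
    stopifnot(is(dm, "DistanceMatrix"))
    format <- match.arg(format)
    v <- dm@values
    labs <- labels(dm)
    n <- nrow(v)
    fmt <- function(x) sprintf("%.17g", x)
    out <- switch(format,
        square_delim = c(paste(c("", labs), collapse = "\t"),
                         vapply(seq_len(n), function(i)
                             paste(c(labs[i], fmt(v[i, ])), collapse = "\t"),
                             character(1))),
        lower_triangular_delim = vapply(seq_len(n), function(i)
            paste(c(labs[i], if (i > 1L) fmt(v[i, seq_len(i - 1L)])),
                  collapse = "\t"), character(1)),
        phylip_dist = {
            if (any(grepl("[[:space:]]", labs)))
                stop("phylip_dist labels must not contain whitespace")
            c(sprintf("%5d", n),
              vapply(seq_len(n), function(i)
                  paste(c(labs[i], fmt(v[i, ])), collapse = "  "),
                  character(1)))
        })
    writeLines(out, path)
    invisible(path)
}

#' Read a run-configuration file
#'
#' Reads clustering parameters from a JSON object or a `key=value` file.
#' Recognized keys (case-insensitive, underscores ignored): `m`, `n_limit`,
#' `max_levels`, `d`, `format`, `input`. Unknown keys are kept verbatim.
#'
#' @param path configuration file.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    cfg <- if (grepl("^\\s*\\{", txt)) {
        jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else {
        lines <- strsplit(txt, "\n")[[1L]]
        lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
        bad <- !grepl("=", lines, fixed = TRUE)
        if (any(bad))
            stop("config line without '=': '", lines[which(bad)[1L]], "'")
        kv <- strsplit(lines, "=", fixed = TRUE)
        vals <- lapply(kv, function(x)
            trimws(paste(x[-1L], collapse = "=")))
        names(vals) <- trimws(vapply(kv, `[[`, character(1), 1L))
        lapply(vals, function(x) {
            num <- suppressWarnings(as.numeric(x))
            if (!is.na(num)) num else x
        })
    }
    canon <- gsub("_", "", tolower(names(cfg)))
    map <- c(m = "m", nlimit = "nLimit", maxlevels = "maxLevels", d = "d",
             format = "format", input = "input")
    names(cfg) <- ifelse(canon %in% names(map), map[canon], names(cfg))
    cfg
}
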