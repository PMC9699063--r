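#' Integrate a hierarchy into an MSC tree
#'
#' Combines all clustering levels into one graph over the original elements.
#' Level-1 edges are the nearest links that formed each group: the group's
#' closest (mutual nearest) pair is the core link, every other member link
#' is a non-core "member" edge; mutual links are collapsed to one undirected
#' edge. For every level >= 2, the nearest-link structure that merged the
#' previous level's groups contributes "inter_cluster" edges, each realized
#' between the specific pair of original elements achieving the minimum
#' cross-group distance (which, because renormalization takes minima of
#' minima, equals the renormalized matrix entry) and annotated with that
#' distance and level.
#'
#' When the run ends in a single group, the undirected edge set is a
#' spanning tree of the n elements: n - 1 edges, acyclic. When it ends in
#' several groups the result is a spanning forest with one tree per final
#' group; no edges are drawn between final-level groups.
#'
#' @param hierarchy an [MSCHierarchy-class] from [runMSC()].
#' @return an [MSCTree-class].
#' @export
buildMSCTree <- function(hierarchy) {
    stopifnot(is(hierarchy, "MSCHierarchy"))
    raw <- hierarchy@levelMatrices[[1L]]@values
    elems <- rownames(raw)
    memb <- hierarchy@membership
    rows <- list()
    for (l in seq_len(nLevels(hierarchy))) {
        cl <- hierarchy@levels[[l]]
        lv <- hierarchy@levelMatrices[[l]]@values
        nn <- cl@memberLinks
        src <- which(!is.na(nn))
        if (!length(src)) next
        a <- pmin(src, nn[src]); b <- pmax(src, nn[src])
        pair <- !duplicated(cbind(a, b))
        a <- a[pair]; b <- b[pair]
        core <- vapply(seq_along(a), function(k) {
            cli <- cl@coreLinks[[cl@nodeGroup[a[k]]]]
            length(cli) == 2L && min(cli) == a[k] && max(cli) == b[k]
        }, logical(1))
        if (l == 1L) {
            rows[[l]] <- data.frame(
                source = elems[a], target = elems[b], level = l,
                kind = ifelse(core, "core", "member"),
                distance = lv[cbind(a, b)])
        } else {
            # anchor each group-level link at the element pair realizing
            # the minimum cross-group distance in the raw matrix
            prevIds <- cl@labels  # group ids of level l-1
            anch <- vapply(seq_along(a), function(k) {
                ea <- which(memb[, l - 1L] == prevIds[a[k]])
                eb <- which(memb[, l - 1L] == prevIds[b[k]])
                sub <- raw[ea, eb, drop = FALSE]
                ij <- arrayInd(which.min(sub), dim(sub))
                c(ea[ij[1L]], eb[ij[2L]], min(sub))
            }, numeric(3))
            rows[[l]] <- data.frame(
                source = elems[anch[1L, ]], target = elems[anch[2L, ]],
                level = l, kind = "inter_cluster", distance = anch[3L, ])
        }
    }
    edges <- do.call(rbind, rows)
    if (is.null(edges))
        edges <- data.frame(source = character(0), target = character(0),
                            level = integer(0), kind = character(0),
                            distance = numeric(0))
    edges <- edges[order(edges$level, edges$source, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    nodes <- data.frame(element = elems, memb, row.names = NULL,
                        check.names = FALSE)
    boxes <- lapply(seq_len(ncol(memb)), function(l)
        split(elems, memb[, l])[unique(memb[, l])])
    names(boxes) <- colnames(memb)
    new("MSCTree", nodes = nodes, edges = edges, clusterBoxes = boxes)
}

#' @rdname MSCTree-class
#' @param x,object an `MSCTree`
#' @export
setMethod("treeEdges", "MSCTree", function(x) x@edges)

#' @rdname MSCTree-class
#' @export
setMethod("treeNodes", "MSCTree", function(x) x@nodes)

#' @rdname MSCTree-class
#' @export
setMethod("clusterBoxes", "MSCTree", function(x) x@clusterBoxes)

setMethod("show", "MSCTree", function(object) {
    tab <- table(object@edges$kind)
    cat(sprintf("MSCTree: %d elements, %d edges (%s)\n",
                nrow(object@nodes), nrow(object@edges),
                paste(names(tab), tab, sep = ": ", collapse = ", ")))
})

# Fixed level -> edge colour convention: level 1 black, 2 red, 3 yellow,
# deeper (inter-cluster at the final levels) green.
.levelColor <- function(level) {
    cols <- c("black", "red", "yellow")
    ifelse(level <= 3L, cols[pmin(level, 3L)], "green")
}

#' Export the MSC tree as an edge-list TSV
#'
#' Columns source, target, level, kind, distance; distances rendered with 6
#' significant digits; rows ordered by level, then source, then target.
#'
#' @param tree an [MSCTree-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
exportEdgeList <- function(tree, path) {
    stopifnot(is(tree, "MSCTree"))
    e <- tree@edges
    e$distance <- formatC(e$distance, digits = 6, format = "g")
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export the MSC tree as GraphML
#'
#' Writes a standard GraphML document importable by Cytoscape and igraph:
#' node attributes hold the group id at every level; edge attributes hold
#' level, kind, distance and a fixed level colour (level 1 black, 2 red,
#' 3 yellow, deeper levels green).
#'
#' @param tree an [MSCTree-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
exportGraphML <- function(tree, path) {
    stopifnot(is(tree, "MSCTree"))
    doc <- xml2::xml_new_root(
        "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
    levCols <- setdiff(names(tree@nodes), "element")
    for (lc in levCols) {
        k <- xml2::xml_add_child(doc, "key", id = paste0("n_", lc),
                                 `for` = "node", `attr.name` = lc,
                                 `attr.type` = "string")
    }
    for (spec in list(c("e_level", "level", "int"),
                      c("e_kind", "kind", "string"),
                      c("e_distance", "distance", "double"),
                      c("e_color", "color", "string"))) {
        xml2::xml_add_child(doc, "key", id = spec[1L], `for` = "edge",
                            `attr.name` = spec[2L], `attr.type` = spec[3L])
    }
    g <- xml2::xml_add_child(doc, "graph", id = "MSCTree",
                             edgedefault = "undirected")
    for (i in seq_len(nrow(tree@nodes))) {
        nd <- xml2::xml_add_child(g, "node", id = tree@nodes$element[i])
        for (lc in levCols) {
            d <- xml2::xml_add_child(nd, "data", key = paste0("n_", lc))
            xml2::xml_set_text(d, tree@nodes[[lc]][i])
        }
    }
    e <- tree@edges
    for (i in seq_len(nrow(e))) {
        ed <- xml2::xml_add_child(g, "edge", source = e$source[i],
                                  target = e$target[i])
        vals <- c(e_level = as.character(e$level[i]), e_kind = e$kind[i],
                  e_distance = sprintf("%.17g", e$distance[i]),
                  e_color = .levelColor(e$level[i]))
        for (k in names(vals)) {
            d <- xml2::xml_add_child(ed, "data", key = k)
            xml2::xml_set_text(d, vals[[k]])
        }
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

.newickSafe <- function(x) gsub("[][ ,:;()']", "_", x)

#' Export a hierarchy as a Newick tree
#'
#' Renders the nested partitions as a Newick string: leaves are the element
#' labels, internal nodes are the groups (labeled "L{level}G{n}"; levels at
#' which a group passes through unchanged are collapsed). The branch length
#' of every child is the minimum cross-set distance, in the original
#' matrix, between the child's members and the members of its siblings -
#' the distance at which the child was linked at the merging level. These
#' lengths are merge distances, not additive path lengths, so the tree is
#' not a dendrogram and no ultrametric correction is applied. If the run
#' ends in several groups they are attached to an unlabeled root.
#'
#' @param hierarchy an [MSCHierarchy-class].
#' @param path output file; `NULL` returns the Newick string instead.
#' @return the Newick string, invisibly when `path` is given.
#' @export
exportNewick <- function(hierarchy, path = NULL) {
    stopifnot(is(hierarchy, "MSCHierarchy"))
    raw <- hierarchy@levelMatrices[[1L]]@values
    memb <- hierarchy@membership
    elems <- rownames(memb)
    L <- nLevels(hierarchy)
    members <- function(l, gid) which(memb[, l] == gid)
    # minimum raw distance between element index sets
    minCross <- function(ea, eb) min(raw[ea, eb, drop = FALSE])
    render <- function(l, gid) {
        # returns the subtree string for group gid at level l, no length
        me <- members(l, gid)
        if (l == 1L && length(me) == 1L)
            return(.newickSafe(elems[me]))  # singleton (outlier) group
        kids <- if (l == 1L) as.list(elems[me])
                else unique(memb[me, l - 1L])
        if (l > 1L && length(kids) == 1L)
            return(render(l - 1L, kids[[1L]]))  # collapse pass-through
        kidSets <- if (l == 1L) lapply(me, identity)
                   else lapply(kids, function(k) members(l - 1L, k))
        parts <- vapply(seq_along(kids), function(i) {
            sibs <- unlist(kidSets[-i])
            len <- if (length(sibs)) minCross(kidSets[[i]], sibs) else 0
            sub <- if (l == 1L) .newickSafe(kids[[i]])
                   else render(l - 1L, kids[[i]])
            sprintf("%s:%.10g", sub, len)
        }, character(1))
        sprintf("(%s)%s", paste(parts, collapse = ","), .newickSafe(gid))
    }
    finals <- unique(memb[, L])
    nwk <- if (length(finals) == 1L) {
        paste0(render(L, finals), ";")
    } else {
        parts <- vapply(finals, function(gid) {
            others <- unlist(lapply(setdiff(finals, gid),
                                    function(o) members(L, o)))
            sprintf("%s:%.10g", render(L, gid),
                    minCross(members(L, gid), others))
        }, character(1))
        sprintf("(%s);", paste(parts, collapse = ","))
    }
    if (is.null(path)) return(nwk)
    writeLines(nwk, path)
    invisible(nwk)
}
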