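#' @rdname DistanceMatrix
#' @param object,x a `DistanceMatrix`
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' Number of groups at a clustering level
#' @param x a `LevelClustering`
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' Group identifiers ("L{level}G{n}")
#' @param x a `LevelClustering`
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' Group members as a named list of label vectors
#' @param x a `LevelClustering` or `MSCHierarchy`
#' @param ... further arguments for methods
#' @export
setGeneric("groupMembers", function(x, ...) standardGeneric("groupMembers"))

#' Labels of outlier nodes
#' @param x a `LevelClustering`
#' @export
setGeneric("outlierLabels", function(x) standardGeneric("outlierLabels"))

#' Number of clustering levels in a hierarchy
#' @param x an `MSCHierarchy`
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' Number of groups at each level of a hierarchy
#' @param x an `MSCHierarchy`
#' @export
setGeneric("groupCounts", function(x) standardGeneric("groupCounts"))

#' Reason the clustering iteration stopped
#' @param x an `MSCHierarchy`
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' Flat partition of the original elements at one level
#'
#' @param x an `MSCHierarchy`
#' @param level integer level, 1-based
#' @return named character vector: element label -> group id
#' @export
setGeneric("cutPartition", function(x, level) standardGeneric("cutPartition"))

#' Membership table of a hierarchy
#' @param x an `MSCHierarchy`
#' @export
setGeneric("membershipTable", function(x) standardGeneric("membershipTable"))

#' Edge table of an MSC tree
#' @param x an `MSCTree`
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' Node table of an MSC tree
#' @param x an `MSCTree`
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' Per-level cluster membership boxes of an MSC tree
#' @param x an `MSCTree`
#' @export
setGeneric("clusterBoxes", function(x) standardGeneric("clusterBoxes"))
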