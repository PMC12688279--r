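#' Identifier accessors
#'
#' `ids()` returns the ordered identifier vector of a single-entity object;
#' `circIds()` / `drugIds()` return the circRNA / drug identifier lists of
#' bipartite objects.
#'
#' @param x a circDrugGCL object.
#' @return character vector of identifiers.
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname ids
#' @export
setGeneric("circIds", function(x) standardGeneric("circIds"))

#' @rdname ids
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @describeIn ids sequences of a SequenceSet (named by id).
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Extract the numeric payload of a matrix-like object
#'
#' Returns the underlying base matrix (association 0/1 matrix, similarity
#' values or fingerprint bits) with identifier dimnames.
#'
#' @param x an `AssociationMatrix`, `SimilarityMatrix` or `FingerprintSet`.
#' @return numeric matrix.
#' @export
setGeneric("valuesMatrix", function(x) standardGeneric("valuesMatrix"))

#' Graph component accessors
#'
#' `edges()` returns the typed weighted edge list of a graph or masked
#' view; `graphViews()` the named adjacency views; `maskedGraph()` the
#' perturbed graph inside a [MaskedView]; `removedEdges()` the indices of
#' the removed base edges.
#'
#' @param x a `HeterogeneousGraph` or `MaskedView`.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname edges
#' @export
setGeneric("graphViews", function(x) standardGeneric("graphViews"))

#' @rdname edges
#' @export
setGeneric("maskedGraph", function(x) standardGeneric("maskedGraph"))

#' @rdname edges
#' @export
setGeneric("removedEdges", function(x) standardGeneric("removedEdges"))

#' Ranking table accessors
#'
#' @param x a `RankingTable`.
#' @return `rankingFrame()` returns the underlying data.frame;
#'   `verificationRate()` the percentage (0-100) of verified entries among
#'   rows with a non-missing verification flag.
#' @export
setGeneric("rankingFrame", function(x) standardGeneric("rankingFrame"))

#' @rdname rankingFrame
#' @export
setGeneric("verificationRate", function(x) standardGeneric("verificationRate"))

#' Metrics report accessors
#'
#' @param x a `MetricsReport`.
#' @return `foldMetrics()` returns the per-fold metric data.frame;
#'   `meanMetrics()` the named vector of metric means.
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname foldMetrics
#' @export
setGeneric("meanMetrics", function(x) standardGeneric("meanMetrics"))
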