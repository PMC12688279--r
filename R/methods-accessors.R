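#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname ids
setMethod("ids", "SequenceSet", function(x) x@ids)
#' @rdname ids
setMethod("ids", "FingerprintSet", function(x) x@ids)
#' @rdname ids
setMethod("ids", "SimilarityMatrix", function(x) x@ids)

#' @rdname ids
setMethod("circIds", "AssociationMatrix", function(x) x@circIds)
#' @rdname ids
setMethod("circIds", "HeterogeneousGraph", function(x) x@circIds)
#' @rdname ids
setMethod("drugIds", "AssociationMatrix", function(x) x@drugIds)
#' @rdname ids
setMethod("drugIds", "HeterogeneousGraph", function(x) x@drugIds)

#' @rdname ids
setMethod("sequences", "SequenceSet",
    function(x) stats::setNames(x@sequences, x@ids))

#' @rdname valuesMatrix
setMethod("valuesMatrix", "AssociationMatrix", function(x) {
    v <- x@values
    dimnames(v) <- list(x@circIds, x@drugIds)
    v
})
#' @rdname valuesMatrix
setMethod("valuesMatrix", "SimilarityMatrix", function(x) {
    v <- x@values
    dimnames(v) <- list(x@ids, x@ids)
    v
})
#' @rdname valuesMatrix
setMethod("valuesMatrix", "FingerprintSet", function(x) {
    v <- x@bits
    rownames(v) <- x@ids
    v
})

#' @rdname edges
setMethod("edges", "HeterogeneousGraph", function(x) x@edges)
#' @rdname edges
setMethod("edges", "MaskedView", function(x) x@graph@edges)
#' @rdname edges
setMethod("graphViews", "HeterogeneousGraph", function(x) x@views)
#' @rdname edges
setMethod("graphViews", "MaskedView", function(x) x@graph@views)
#' @rdname edges
setMethod("maskedGraph", "MaskedView", function(x) x@graph)
#' @rdname edges
setMethod("removedEdges", "MaskedView", function(x) x@removedEdges)

#' @rdname rankingFrame
setMethod("rankingFrame", "RankingTable", function(x) x@table)

#' @rdname rankingFrame
setMethod("verificationRate", "RankingTable", function(x) {
    v <- x@table$verified
    v <- v[!is.na(v)]
    if (!length(v))
        stop("no verification flags present in ranking table")
    100 * mean(v)
})

#' @rdname foldMetrics
setMethod("foldMetrics", "MetricsReport", function(x) x@perFold)
#' @rdname foldMetrics
setMethod("meanMetrics", "MetricsReport", function(x) x@summary)

setMethod("show", "SequenceSet", function(object) {
    cat(sprintf("SequenceSet with %d sequences (lengths %d..%d)\n",
                length(object@ids),
                if (length(object@ids)) min(nchar(object@sequences)) else 0L,
                if (length(object@ids)) max(nchar(object@sequences)) else 0L))
})

setMethod("show", "FingerprintSet", function(object) {
    cat(sprintf("FingerprintSet with %d drugs, %d bits\n",
                length(object@ids), ncol(object@bits)))
})

setMethod("show", "AssociationMatrix", function(object) {
    v <- object@values
    cat(sprintf(
        "AssociationMatrix: %d circRNAs x %d drugs, %d positives (density %.4f)\n",
        nrow(v), ncol(v), sum(v), mean(v)))
})

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix (%s) over %d entities\n",
                object@source, length(object@ids)))
})

setMethod("show", "HeterogeneousGraph", function(object) {
    tab <- table(factor(object@edges$type, levels = c("cc", "dd", "cd")))
    cat(sprintf(
        "HeterogeneousGraph: %d circRNAs + %d drugs; edges cc=%d dd=%d cd=%d (knnK=%g)\n",
        length(object@circIds), length(object@drugIds),
        tab[["cc"]], tab[["dd"]], tab[["cd"]], object@knnK))
})

setMethod("show", "MaskedView", function(object) {
    cat(sprintf(
        "MaskedView (%s mask, intensity %.2f, seed %d): removed %d of %d edges\n",
        object@strategy, object@intensity, object@seed,
        length(object@removedEdges), nrow(object@base@edges)))
})

setMethod("show", "RankingTable", function(object) {
    cat(sprintf("RankingTable for drug '%s' (top %d)\n",
                object@drugId, nrow(object@table)))
    print(utils::head(object@table, 5L))
    if (nrow(object@table) > 5L) cat("...\n")
})

setMethod("show", "MetricsReport", function(object) {
    cat(sprintf("MetricsReport: %d-fold cross-validation\n",
                nrow(object@perFold)))
    print(round(object@summary, 4))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: M=%d N=%d rank=%d density=%.3f seqLen=%d fpLen=%d noise=%.2f seed=%d\n",
        object@M, object@N, object@rank, object@density, object@seqLen,
        object@fpLen, object@noise, object@seed))
})

setMethod("show", "ModelConfig", function(object) {
    cat("ModelConfig\n")
    for (g in c("encoder", "mask", "loss", "afc", "train", "cv",
                "features", "ablation")) {
        s <- slot(object, g)
        cat(sprintf("  %-9s %s\n", paste0(g, ":"),
                    paste(names(s), unlist(lapply(s, format)),
                          sep = "=", collapse = " ")))
    }
})
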