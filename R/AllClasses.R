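#' @import methods
NULL

.SIM_SOURCES <- c("sequence", "gip", "structure", "fused")

#' SequenceSet: circRNA host-gene sequences
#'
#' Ordered collection of nucleotide sequences, one per circRNA identifier.
#' Sequences are uppercase strings over the alphabet `A,C,G,T,N`; `U` is
#' mapped to `T` on import so RNA-style FASTA records are accepted.
#'
#' @slot ids character vector of unique circRNA identifiers.
#' @slot sequences character vector of non-empty uppercase sequences,
#'   parallel to `ids`.
#'
#' @seealso [readFasta()], [sequenceSimilarity()]
#' @export
setClass("SequenceSet",
    representation(ids = "character", sequences = "character"))

setValidity("SequenceSet", function(object) {
    msg <- character()
    if (length(object@ids) != length(object@sequences))
        msg <- c(msg, "ids and sequences must have equal length")
    if (anyDuplicated(object@ids))
        msg <- c(msg, sprintf("duplicate identifier: %s",
                              object@ids[duplicated(object@ids)][1L]))
    if (any(!nzchar(object@sequences)))
        msg <- c(msg, "sequences must be non-empty")
    bad <- grepl("[^ACGTN]", object@sequences)
    if (any(bad))
        msg <- c(msg, sprintf(
            "record '%s' contains characters outside {A,C,G,T,N}",
            object@ids[bad][1L]))
    if (length(msg)) msg else TRUE
})

#' FingerprintSet: binary drug fingerprints
#'
#' Ordered set of drug topological fingerprints as a binary bit matrix with
#' one row per drug and a common bit length.
#'
#' @slot ids character vector of unique drug identifiers.
#' @slot bits numeric 0/1 matrix, one row per drug.
#'
#' @seealso [readFingerprints()], [tanimotoSimilarity()]
#' @export
setClass("FingerprintSet",
    representation(ids = "character", bits = "matrix"))

setValidity("FingerprintSet", function(object) {
    msg <- character()
    if (nrow(object@bits) != length(object@ids))
        msg <- c(msg, "bit matrix must have one row per identifier")
    if (anyDuplicated(object@ids))
        msg <- c(msg, "duplicate drug identifier")
    if (ncol(object@bits) < 1L)
        msg <- c(msg, "fingerprint length must be >= 1")
    if (!all(object@bits %in% c(0, 1)))
        msg <- c(msg, "fingerprint entries must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' AssociationMatrix: binary circRNA-drug sensitivity associations
#'
#' The M x N 0/1 matrix `A` of known circRNA-drug sensitivity associations,
#' with aligned row (circRNA) and column (drug) identifier lists.  Row and
#' column order defines index order everywhere downstream.
#'
#' @slot circIds character, M unique circRNA identifiers (rows).
#' @slot drugIds character, N unique drug identifiers (columns).
#' @slot values numeric M x N matrix with entries in `{0,1}`.
#'
#' @seealso [readAssociationMatrix()], [gipSimilarity()], [makeFolds()]
#' @export
setClass("AssociationMatrix",
    representation(circIds = "character", drugIds = "character",
                   values = "matrix"))

setValidity("AssociationMatrix", function(object) {
    msg <- character()
    M <- length(object@circIds); N <- length(object@drugIds)
    if (M < 1L || N < 1L)
        msg <- c(msg, "matrix must be at least 1 x 1")
    if (!identical(dim(object@values), c(M, N)))
        msg <- c(msg, "values dimensions must match identifier lists")
    if (anyDuplicated(object@circIds) || anyDuplicated(object@drugIds))
        msg <- c(msg, "identifiers must be unique per axis")
    if (!all(object@values %in% c(0, 1)))
        msg <- c(msg, "association values must be binary")
    if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: square symmetric similarity over one entity type
#'
#' A symmetric n x n matrix with values in `[0,1]` over circRNAs or drugs,
#' tagged with its source (sequence edit distance, GIP kernel, fingerprint
#' structure, or a conditional fusion of these).
#'
#' @slot ids character identifiers (size n).
#' @slot values numeric n x n matrix, symmetric within 1e-9, entries in
#'   `[0,1]`; unit diagonal for the `sequence`, `gip` and `structure`
#'   sources.
#' @slot source one of `"sequence"`, `"gip"`, `"structure"`, `"fused"`.
#'
#' @export
setClass("SimilarityMatrix",
    representation(ids = "character", values = "matrix",
                   source = "character"))

setValidity("SimilarityMatrix", function(object) {
    msg <- character()
    n <- length(object@ids)
    v <- object@values
    if (!identical(dim(v), c(n, n)))
        msg <- c(msg, "values must be n x n with n = length(ids)")
    if (!(object@source %in% .SIM_SOURCES))
        msg <- c(msg, sprintf("source must be one of %s",
                              paste(.SIM_SOURCES, collapse = ", ")))
    if (n > 0L) {
        if (max(abs(v - t(v))) > 1e-9)
            msg <- c(msg, "values must be symmetric within 1e-9")
        if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
            msg <- c(msg, "values must lie in [0,1]")
        if (object@source != "fused" && max(abs(diag(v) - 1)) > 1e-9)
            msg <- c(msg, "diagonal must equal 1 for this source")
    }
    if (length(msg)) msg else TRUE
})

#' BandwidthParam: GIP kernel bandwidth
#'
#' The Gaussian interaction profile kernel bandwidth, the inverse of the
#' mean squared Euclidean norm of the association profiles along one axis.
#'
#' @slot value positive finite bandwidth.
#' @slot axis `"circ_rows"` or `"drug_cols"`.
#' @export
setClass("BandwidthParam",
    representation(value = "numeric", axis = "character"))

setValidity("BandwidthParam", function(object) {
    if (length(object@value) != 1L || !is.finite(object@value) ||
        object@value <= 0)
        return("bandwidth must be a single positive finite value")
    if (!(object@axis %in% c("circ_rows", "drug_cols")))
        return("axis must be 'circ_rows' or 'drug_cols'")
    TRUE
})

#' HeterogeneousGraph: the circRNA-drug network
#'
#' Typed node set (circRNAs then drugs), typed weighted undirected edges
#' (circ-circ similarity, drug-drug similarity, circ-drug association) plus
#' fused per-node feature blocks, and the three materialized adjacency
#' views over the joint node set consumed by the encoder.
#'
#' Node indices are global: circRNAs occupy `1..M`, drugs `M+1..M+N`.
#' Self-loops are *not* stored; they are added at adjacency normalization
#' time.
#'
#' @slot circIds,drugIds identifier vectors.
#' @slot Xc numeric M x M fused circRNA feature block.
#' @slot Xd numeric N x N fused drug feature block.
#' @slot edges data.frame with columns `type` (`"cc"`,`"dd"`,`"cd"`), `i`,
#'   `j` (global node indices, `i < j`) and weight `w`.
#' @slot views named list of three (M+N) x (M+N) adjacency matrices:
#'   `circ_sim`, `drug_sim`, `association`.
#' @slot knnK the mutual k-NN sparsification parameter used.
#'
#' @seealso [buildGraph()], [maskPath()], [maskEdge()]
#' @export
setClass("HeterogeneousGraph",
    representation(circIds = "character", drugIds = "character",
                   Xc = "matrix", Xd = "matrix",
                   edges = "data.frame", views = "list",
                   knnK = "numeric"))

setValidity("HeterogeneousGraph", function(object) {
    msg <- character()
    M <- length(object@circIds); N <- length(object@drugIds)
    e <- object@edges
    need <- c("type", "i", "j", "w")
    if (!all(need %in% names(e)))
        msg <- c(msg, "edges must have columns type, i, j, w")
    else if (nrow(e)) {
        if (any(e$i == e$j))
            msg <- c(msg, "self-edges are not allowed")
        if (any(e$i >= e$j))
            msg <- c(msg, "edges must be stored with i < j")
        if (any(e$w[e$type == "cd"] != 1))
            msg <- c(msg, "association edges must have weight 1")
        wsim <- e$w[e$type != "cd"]
        if (length(wsim) && (any(wsim <= 0) || any(wsim > 1)))
            msg <- c(msg, "similarity edge weights must lie in (0,1]")
    }
    if (!identical(sort(names(object@views)),
                   sort(c("circ_sim", "drug_sim", "association"))))
        msg <- c(msg, "views must be circ_sim, drug_sim, association")
    else if (!all(vapply(object@views, function(v)
                         identical(dim(v), c(M + N, M + N)), logical(1))))
        msg <- c(msg, "each view must be (M+N) x (M+N)")
    if (!identical(dim(object@Xc), c(M, M)) ||
        !identical(dim(object@Xd), c(N, N)))
        msg <- c(msg, "feature blocks must be M x M and N x N")
    if (length(msg)) msg else TRUE
})

#' MaskedView: a stochastically masked copy of the graph
#'
#' A perturbed [HeterogeneousGraph] produced by path masking or edge
#' masking, with full provenance so the perturbation can be replayed
#' bit-identically.
#'
#' @slot base the unperturbed graph.
#' @slot strategy `"path"` or `"edge"`.
#' @slot intensity masking intensity in `[0,1]` (alpha or beta).
#' @slot seed integer RNG seed that generated the mask.
#' @slot removedEdges integer row indices into `edges(base)`.
#' @slot graph the perturbed graph (edges removed, adjacency views zeroed;
#'   node set and features untouched).
#'
#' @seealso [maskPath()], [maskEdge()]
#' @export
setClass("MaskedView",
    representation(base = "HeterogeneousGraph", strategy = "character",
                   intensity = "numeric", seed = "integer",
                   removedEdges = "integer", graph = "HeterogeneousGraph"))

setValidity("MaskedView", function(object) {
    msg <- character()
    if (!(object@strategy %in% c("path", "edge")))
        msg <- c(msg, "strategy must be 'path' or 'edge'")
    if (object@intensity < 0 || object@intensity > 1)
        msg <- c(msg, "intensity must lie in [0,1]")
    nb <- nrow(object@base@edges)
    if (length(object@removedEdges) &&
        (min(object@removedEdges) < 1L || max(object@removedEdges) > nb))
        msg <- c(msg, "removedEdges must index rows of the base edge set")
    if (object@intensity == 0 && length(object@removedEdges))
        msg <- c(msg, "zero intensity must remove no edges")
    if (nrow(object@graph@edges) != nb - length(object@removedEdges))
        msg <- c(msg, "masked edge set must equal base minus removed")
    if (length(msg)) msg else TRUE
})

#' RankingTable: top-k candidate circRNAs for one drug
#'
#' Prediction-score ranking of candidate circRNAs for a single drug, with
#' an optional external verification flag column.
#'
#' @slot drugId the drug the ranking is for.
#' @slot table data.frame with columns `rank` (consecutive from 1),
#'   `circRNA`, `score` (non-increasing, in `[0,1]`) and `verified`
#'   (logical, may be `NA` when no curation is available).
#'
#' @seealso [rankCandidates()], [writeRanking()], [verificationRate()]
#' @export
setClass("RankingTable",
    representation(drugId = "character", table = "data.frame"))

setValidity("RankingTable", function(object) {
    tb <- object@table
    msg <- character()
    need <- c("rank", "circRNA", "score", "verified")
    if (!all(need %in% names(tb)))
        return("table must have columns rank, circRNA, score, verified")
    if (nrow(tb)) {
        if (!identical(as.integer(tb$rank), seq_len(nrow(tb))))
            msg <- c(msg, "ranks must be consecutive from 1")
        if (any(diff(tb$score) > 1e-12))
            msg <- c(msg, "scores must be non-increasing with rank")
        if (any(tb$score < -1e-12 | tb$score > 1 + 1e-12))
            msg <- c(msg, "scores must lie in [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' MetricsReport: cross-validation metrics
#'
#' Per-fold and mean AUC, AUPR, F1, Accuracy and Recall from a k-fold
#' cross-validation run, together with the fold assignments and a snapshot
#' of the configuration that produced them.
#'
#' @slot perFold data.frame, one row per fold, columns `fold`, `AUC`,
#'   `AUPR`, `F1`, `Accuracy`, `Recall`.
#' @slot summary named numeric vector of metric means over folds.
#' @slot folds the fold assignment data.frame (pair indices, label, fold).
#' @slot config configuration snapshot (named list).
#' @slot foldSafe TRUE iff the leakage assertion (test positives zeroed
#'   before feature recomputation) held in every fold.
#'
#' @seealso [crossValidate()]
#' @export
setClass("MetricsReport",
    representation(perFold = "data.frame", summary = "numeric",
                   folds = "data.frame", config = "list",
                   foldSafe = "logical"))

setValidity("MetricsReport", function(object) {
    msg <- character()
    mets <- c("AUC", "AUPR", "F1", "Accuracy", "Recall")
    if (!all(mets %in% names(object@perFold)))
        return("perFold must contain AUC, AUPR, F1, Accuracy, Recall")
    vals <- unlist(object@perFold[mets])
    if (length(vals) && (any(vals < 0) || any(vals > 1)))
        msg <- c(msg, "metrics must lie in [0,1]")
    if (nrow(object@perFold)) {
        mu <- colMeans(object@perFold[mets])
        if (max(abs(mu - object@summary[mets])) > 1e-9)
            msg <- c(msg, "summary must be the arithmetic mean of folds")
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic benchmark generator
#'
#' @slot M,N numbers of circRNAs and drugs.
#' @slot rank latent dimension / number of planted clusters.
#' @slot density target positive rate of the association matrix.
#' @slot seqLen generated host-gene sequence length.
#' @slot fpLen fingerprint bit length.
#' @slot noise probability that a planted association is masked (dropped
#'   to 0), emulating incomplete association annotation.
#' @slot seed RNG seed; the dataset is fully determined by it.
#'
#' @seealso [generateDataset()], [benchmarkSpec()]
#' @export
setClass("SyntheticSpec",
    representation(M = "integer", N = "integer", rank = "integer",
                   density = "numeric", seqLen = "integer",
                   fpLen = "integer", noise = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@M < 2L || object@N < 2L)
        msg <- c(msg, "M and N must be >= 2")
    if (object@rank < 1L)
        msg <- c(msg, "rank must be >= 1")
    if (object@density <= 0 || object@density >= 1)
        msg <- c(msg, "density must lie in (0,1)")
    if (object@noise < 0 || object@noise >= 0.5)
        msg <- c(msg, "noise must lie in [0, 0.5)")
    if (object@seqLen < 1L || object@fpLen < 1L)
        msg <- c(msg, "seqLen and fpLen must be >= 1")
    if (length(msg)) msg else TRUE
})

#' ModelConfig: all model and training hyperparameters
#'
#' Grouped hyperparameter container; construct with [modelConfig()], which
#' fills defaults.  Groups: `encoder` (layers, hiddenDim, dropout), `mask`
#' (alpha, beta, walkLen, resampleEachEpoch), `loss` (tauMax, tauMin,
#' lambdaC, denominator), `afc` (heads, dim, pairFeatures, batchSize),
#' `train` (epochs, lr, seed, negRatio), `cv` (folds), `features` (knnK,
#' gipBandwidth, leakyGip), `ablation` (useMaskPath, useMaskEdge, useAfc,
#' useGat, useGcn).
#'
#' @export
setClass("ModelConfig",
    representation(encoder = "list", mask = "list", loss = "list",
                   afc = "list", train = "list", cv = "list",
                   features = "list", ablation = "list"))

setValidity("ModelConfig", function(object) {
    msg <- character()
    e <- object@encoder; m <- object@mask; l <- object@loss
    a <- object@afc; tr <- object@train; cv <- object@cv
    if (e$layers < 1L) msg <- c(msg, "encoder.layers must be >= 1")
    if (e$hiddenDim < 1L) msg <- c(msg, "encoder.hiddenDim must be >= 1")
    if (e$dropout < 0 || e$dropout >= 1)
        msg <- c(msg, "encoder.dropout must lie in [0,1)")
    if (m$alpha < 0 || m$alpha > 1 || m$beta < 0 || m$beta > 1)
        msg <- c(msg, "mask intensities must lie in [0,1]")
    if (m$walkLen < 1L) msg <- c(msg, "mask.walkLen must be >= 1")
    if (!(l$tauMax >= l$tauMin && l$tauMin > 0))
        msg <- c(msg, "need tauMax >= tauMin > 0")
    if (l$lambdaC < 0) msg <- c(msg, "loss.lambdaC must be >= 0")
    if (!(l$denominator %in% c("incl_positive", "negatives_only")))
        msg <- c(msg, "loss.denominator must be incl_positive or negatives_only")
    if (a$heads < 1L || a$dim %% a$heads != 0)
        msg <- c(msg, "afc.dim must be divisible by afc.heads")
    if (!(a$attentionScope %in% c("per_pair", "batch")))
        msg <- c(msg, "afc.attentionScope must be per_pair or batch")
    if (tr$epochs < 1L) msg <- c(msg, "train.epochs must be >= 1")
    if (tr$lr <= 0) msg <- c(msg, "train.lr must be > 0")
    if (tr$negRatio <= 0) msg <- c(msg, "train.negRatio must be > 0")
    if (!(cv$folds %in% c(5L, 10L)))
        msg <- c(msg, "cv.folds must be 5 or 10")
    if (length(msg)) msg else TRUE
})
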