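#' Sequence similarity from edit distance
#'
#' Pairwise circRNA host-gene similarity
#' `1 - Levenshtein(Seq_i, Seq_j) / max(|Seq_i|, |Seq_j|)` with unit
#' insertion/deletion/substitution costs.  Symmetric with unit diagonal.
#'
#' @param seqs a [SequenceSet].
#' @return a [SimilarityMatrix] with source `"sequence"`.
#' @examples
#' s <- SequenceSet(c("a", "b"), c("ACGT", "ACGA"))
#' valuesMatrix(sequenceSimilarity(s))
#' @export
sequenceSimilarity <- function(seqs) {
    if (any(!nzchar(seqs@sequences)))
        stopTyped("preconditionError", "sequences must be non-empty")
    d <- utils::adist(seqs@sequences)
    len <- nchar(seqs@sequences)
    maxLen <- outer(len, len, pmax)
    sim <- 1 - d / maxLen
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 1
    SimilarityMatrix(seqs@ids, sim, "sequence")
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Similarity between association profiles along one axis of the
#' association matrix: `exp(-eta * ||p_i - p_j||^2)` with `p_i` the i-th
#' row (circRNAs) or column (drugs) of `A`.  The bandwidth `eta` is the
#' inverse of the mean squared Euclidean norm of the profiles; the
#' `"literal"` setting keeps the mean squared norm itself as the
#' bandwidth for audit (see the methods vignette for why the inverse is
#' the default reading).
#'
#' @param A an [AssociationMatrix].
#' @param axis `"circ"` for row profiles, `"drug"` for column profiles.
#' @param bandwidth `"inverse"` (default) or `"literal"`.
#' @return list with elements `sim` (a [SimilarityMatrix], source
#'   `"gip"`) and `bandwidth` (a [BandwidthParam]).
#' @examples
#' A <- AssociationMatrix(c("c1", "c2"), c("d1", "d2"), diag(2))
#' gipSimilarity(A, "circ")$sim
#' @export
gipSimilarity <- function(A, axis = c("circ", "drug"),
                          bandwidth = c("inverse", "literal")) {
    axis <- match.arg(axis)
    bandwidth <- match.arg(bandwidth)
    P <- if (axis == "circ") A@values else t(A@values)
    entityIds <- if (axis == "circ") A@circIds else A@drugIds
    sq <- rowSums(P^2)
    meanSq <- mean(sq)
    if (meanSq == 0)
        stopTyped("undefinedBandwidthError",
                  "all-zero association matrix: GIP bandwidth undefined")
    eta <- if (bandwidth == "inverse") 1 / meanSq else meanSq
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
    D2[D2 < 0] <- 0
    sim <- exp(-eta * D2)
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 1
    list(sim = SimilarityMatrix(entityIds, sim, "gip"),
         bandwidth = new("BandwidthParam", value = eta,
                         axis = if (axis == "circ") "circ_rows"
                                else "drug_cols"))
}

#' Tanimoto similarity between binary fingerprints
#'
#' `|F_i & F_j| / |F_i | F_j|` over the set bits of each fingerprint
#' pair.  Fingerprints with no set bit are rejected (the 0/0 case is
#' declared invalid input rather than silently defined).
#'
#' @param fps a [FingerprintSet].
#' @return a [SimilarityMatrix] with source `"structure"`.
#' @export
tanimotoSimilarity <- function(fps) {
    B <- fps@bits
    nbits <- rowSums(B)
    if (any(nbits == 0))
        stopTyped("preconditionError",
                  "fingerprint '%s' has no set bits",
                  fps@ids[nbits == 0][1L])
    inter <- tcrossprod(B)
    uni <- outer(nbits, nbits, "+") - inter
    sim <- inter / uni
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 1
    SimilarityMatrix(fps@ids, sim, "structure")
}

#' Conditional fusion of a primary similarity with the GIP kernel
#'
#' Entry-wise: the average of the primary (sequence or structure)
#' similarity and the GIP similarity where *both* entities have primary
#' information available, otherwise the GIP similarity alone.
#'
#' @param primary a [SimilarityMatrix] (sequence or structure source).
#' @param gip a [SimilarityMatrix] with source `"gip"` over the same ids
#'   in the same order.
#' @param available logical vector flagging which entities have primary
#'   information (default: all).
#' @return numeric feature block (symmetric matrix with id dimnames).
#' @export
fuseSimilarities <- function(primary, gip,
                             available = rep(TRUE, length(gip@ids))) {
    if (!identical(primary@ids, gip@ids))
        stopTyped("alignmentError",
                  "primary and GIP similarity ids must match in order")
    both <- outer(available, available, "&")
    X <- ifelse(both, (primary@values + gip@values) / 2, gip@values)
    dimnames(X) <- list(gip@ids, gip@ids)
    X
}

# top-k neighbour sets by similarity, self excluded; ties broken by
# identifier (index) order for determinism
.topK <- function(S, k) {
    n <- nrow(S)
    lapply(seq_len(n), function(i) {
        s <- S[i, ]
        s[i] <- -Inf
        ord <- order(s, seq_len(n), decreasing = c(TRUE, FALSE),
                     method = "radix")
        ord[seq_len(min(k, n - 1L))]
    })
}

# mutualized (union) k-NN edge list within one entity block
.knnEdges <- function(X, k, offset, type) {
    n <- nrow(X)
    if (k <= 0L || n < 2L)
        return(data.frame(type = character(), i = integer(),
                          j = integer(), w = numeric()))
    nb <- .topK(X, k)
    pairs <- unique(do.call(rbind, lapply(seq_len(n), function(i) {
        js <- nb[[i]]
        cbind(pmin(i, js), pmax(i, js))
    })))
    w <- X[pairs]
    keep <- w > 0
    data.frame(type = type, i = offset + pairs[keep, 1L],
               j = offset + pairs[keep, 2L], w = w[keep],
               stringsAsFactors = FALSE)
}

#' Assemble the heterogeneous circRNA-drug graph
#'
#' Association edges are exactly the 1-entries of `A`; circ-circ and
#' drug-drug edges are a mutual-k-NN sparsification of the fused feature
#' blocks (an edge is kept when either endpoint ranks the other in its
#' top-k by similarity, self excluded; ties broken by identifier order),
#' weighted by the similarity value.  Zero-similarity pairs are never
#' turned into edges.  The three adjacency views (`circ_sim`,
#' `drug_sim`, `association`) over the joint node set are materialized
#' for the encoder; self-loops are added only at normalization time.
#'
#' @param Xc fused M x M circRNA feature block (from
#'   [fuseSimilarities()]).
#' @param Xd fused N x N drug feature block.
#' @param A an [AssociationMatrix].
#' @param knnK neighbours per node for similarity-edge sparsification;
#'   `0` keeps association edges only; values `>= n` are capped with a
#'   warning.  `Inf` requests the dense mode (every positive-similarity
#'   pair becomes an edge).
#' @return a [HeterogeneousGraph].
#' @export
buildGraph <- function(Xc, Xd, A, knnK = 10L) {
    M <- nrow(A@values); N <- ncol(A@values)
    if (nrow(Xc) != M || nrow(Xd) != N)
        stopTyped("alignmentError",
                  "feature block sizes must match the association matrix")
    capK <- function(k, n) {
        if (is.infinite(k)) return(n - 1L)
        if (k >= n) {
            warning(sprintf("knnK = %d >= n = %d; capped at %d",
                            k, n, n - 1L))
            return(n - 1L)
        }
        as.integer(k)
    }
    eCC <- .knnEdges(Xc, capK(knnK, M), 0L, "cc")
    eDD <- .knnEdges(Xd, capK(knnK, N), M, "dd")
    pos <- which(A@values == 1, arr.ind = TRUE)
    eCD <- data.frame(type = rep("cd", nrow(pos)), i = pos[, 1L],
                      j = M + pos[, 2L], w = rep(1, nrow(pos)),
                      stringsAsFactors = FALSE)
    edges <- rbind(eCC, eDD, eCD)
    edges <- edges[order(match(edges$type, c("cc", "dd", "cd")),
                         edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
    g <- new("HeterogeneousGraph", circIds = A@circIds,
             drugIds = A@drugIds, Xc = Xc, Xd = Xd, edges = edges,
             views = .materializeViews(edges, M, N),
             knnK = as.numeric(knnK))
    g
}

.materializeViews <- function(edges, M, N) {
    n <- M + N
    mk <- function(type) {
        V <- matrix(0, n, n)
        e <- edges[edges$type == type, , drop = FALSE]
        if (nrow(e)) {
            V[cbind(e$i, e$j)] <- e$w
            V[cbind(e$j, e$i)] <- e$w
        }
        V
    }
    list(circ_sim = mk("cc"), drug_sim = mk("dd"), association = mk("cd"))
}
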