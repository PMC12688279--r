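#' Cross-modal multi-head attention fusion of pair features
#'
#' Projects circRNA-side pair features to queries `U` and drug-side pair
#' features to keys `S` and values `T` (`U = Fcirc P_U`,
#' `S = Fdrug P_S`, `T = Fdrug P_T`), splits all three into `h` heads of
#' width `d_h = d/h`, applies scaled dot-product attention
#' (`1/sqrt(d_h)` scaling), and concatenates the head outputs through the
#' output projection `P_O`.  Every attention weight row sums to 1.
#'
#' Two attention scopes are available:
#' \describe{
#'   \item{`per_pair` (default)}{attention is computed within each
#'     candidate pair, across the `h` feature chunks: for every sample
#'     the query chunks attend over that sample's key chunks
#'     (`h x h` weights per sample).  Scores depend only on the pair
#'     itself, so inference is independent of batch composition.}
#'   \item{`batch`}{the literal reading of the fusion equations: per
#'     head, queries attend over the `n` samples of the batch
#'     (`G_i = softmax(U_i S_i'/sqrt(d_h))` is `n x n`).  This couples
#'     every sample's fused features to the rest of the batch; kept for
#'     audit and comparison (see the methods vignette).}
#' }
#'
#' @param Fcirc n x dCirc circRNA-side pair features.
#' @param Fdrug n x dDrug drug-side pair features.
#' @param params parameter list holding `afc.Pu`, `afc.Ps`, `afc.Pt`,
#'   `afc.Po` (see [initModelParams()]).
#' @param heads number of attention heads; must divide the latent width.
#' @param scope `"per_pair"` or `"batch"`.
#' @param cache if TRUE, also return the forward cache used by the
#'   internal backward pass.
#' @return list with `C` (n x d fused matrix) and `G` (attention
#'   weights: per head an `n x n` matrix for `"batch"` scope; per query
#'   chunk an `n x h` matrix for `"per_pair"` scope).
#' @export
attentionFuse <- function(Fcirc, Fdrug, params, heads = 4L,
                          scope = c("per_pair", "batch"),
                          cache = FALSE) {
    scope <- match.arg(scope)
    d <- ncol(params[["afc.Pu"]])
    if (d %% heads != 0)
        stopTyped("configError", "latent dim %d not divisible by %d heads",
                  d, heads)
    if (nrow(Fcirc) != nrow(Fdrug))
        stopTyped("shapeError", "pair feature blocks must align by row")
    U <- Fcirc %*% params[["afc.Pu"]]
    S <- Fdrug %*% params[["afc.Ps"]]
    Tm <- Fdrug %*% params[["afc.Pt"]]
    dh <- d %/% heads
    n <- nrow(U)
    chunk <- function(i) (i - 1L) * dh + seq_len(dh)
    O <- matrix(0, n, d)
    if (scope == "batch") {
        G <- vector("list", heads)
        for (i in seq_len(heads)) {
            idx <- chunk(i)
            logits <- tcrossprod(U[, idx, drop = FALSE],
                                 S[, idx, drop = FALSE]) / sqrt(dh)
            G[[i]] <- softmaxRows(logits)
            O[, idx] <- G[[i]] %*% Tm[, idx, drop = FALSE]
        }
    } else {
        # per sample: query chunk i attends over key chunks j (h x h)
        G <- vector("list", heads)
        for (i in seq_len(heads)) {
            logits <- matrix(0, n, heads)
            for (j in seq_len(heads))
                logits[, j] <- rowSums(U[, chunk(i), drop = FALSE] *
                                       S[, chunk(j), drop = FALSE]) /
                               sqrt(dh)
            G[[i]] <- softmaxRows(logits)
            for (j in seq_len(heads))
                O[, chunk(i)] <- O[, chunk(i)] +
                    G[[i]][, j] * Tm[, chunk(j), drop = FALSE]
        }
    }
    C <- O %*% params[["afc.Po"]]
    out <- list(C = C, G = G)
    if (cache)
        out$cache <- list(U = U, S = S, Tm = Tm, O = O, G = G, dh = dh,
                          heads = heads, scope = scope, Fcirc = Fcirc,
                          Fdrug = Fdrug)
    out
}

attentionFuseBackward <- function(dC, cc, params) {
    grads <- list()
    grads[["afc.Po"]] <- crossprod(cc$O, dC)
    dO <- tcrossprod(dC, params[["afc.Po"]])
    dU <- matrix(0, nrow(dO), ncol(cc$U))
    dS <- matrix(0, nrow(dO), ncol(cc$S))
    dT <- matrix(0, nrow(dO), ncol(cc$Tm))
    sq <- sqrt(cc$dh)
    h <- cc$heads
    chunk <- function(i) (i - 1L) * cc$dh + seq_len(cc$dh)
    if (cc$scope == "batch") {
        for (i in seq_len(h)) {
            idx <- chunk(i)
            Gi <- cc$G[[i]]
            dOi <- dO[, idx, drop = FALSE]
            dG <- tcrossprod(dOi, cc$Tm[, idx, drop = FALSE])
            dT[, idx] <- crossprod(Gi, dOi)
            dLog <- Gi * (dG - rowSums(dG * Gi))
            dU[, idx] <- dLog %*% cc$S[, idx, drop = FALSE] / sq
            dS[, idx] <- crossprod(dLog, cc$U[, idx, drop = FALSE]) / sq
        }
    } else {
        for (i in seq_len(h)) {
            Gi <- cc$G[[i]]                       # n x h
            dOi <- dO[, chunk(i), drop = FALSE]
            dG <- matrix(0, nrow(dO), h)
            for (j in seq_len(h)) {
                dG[, j] <- rowSums(dOi * cc$Tm[, chunk(j), drop = FALSE])
                dT[, chunk(j)] <- dT[, chunk(j)] + Gi[, j] * dOi
            }
            dLog <- Gi * (dG - rowSums(dG * Gi))
            for (j in seq_len(h)) {
                dU[, chunk(i)] <- dU[, chunk(i)] +
                    dLog[, j] * cc$S[, chunk(j), drop = FALSE] / sq
                dS[, chunk(j)] <- dS[, chunk(j)] +
                    dLog[, j] * cc$U[, chunk(i), drop = FALSE] / sq
            }
        }
    }
    grads[["afc.Pu"]] <- crossprod(cc$Fcirc, dU)
    grads[["afc.Ps"]] <- crossprod(cc$Fdrug, dS)
    grads[["afc.Pt"]] <- crossprod(cc$Fdrug, dT)
    grads$dFcirc <- tcrossprod(dU, params[["afc.Pu"]])
    grads$dFdrug <- tcrossprod(dS, params[["afc.Ps"]]) +
                    tcrossprod(dT, params[["afc.Pt"]])
    grads
}

#' Batch-normalized MLP classification head
#'
#' `L1 = ReLU(C A1 + c1)`, batch-normalized to `L1'`;
#' `L2 = ReLU(L1' A2 + c2)`, batch-normalized to `L2'`;
#' `Y = softmax(L2' A3 + c3)`.  In train mode batch statistics are used
#' and the running statistics in `state` are updated; in eval mode the
#' running statistics are applied, so repeated calls are deterministic.
#'
#' @param C fused feature matrix (n x d).
#' @param params parameter list holding `clf.*` entries.
#' @param mode `"train"` or `"eval"`.
#' @param state batch-norm running statistics, as returned in the output
#'   (create with `classifierInitState`); defaults to fresh state.
#' @param cache if TRUE also return the forward cache.
#' @return list with `Y` (n x 2 row-stochastic probability matrix) and
#'   `state` (updated running statistics).
#' @export
classify <- function(C, params, mode = c("eval", "train"), state = NULL,
                     cache = FALSE) {
    mode <- match.arg(mode)
    if (!all(is.finite(C)))
        stopTyped("domainError", "classifier input must be finite")
    train <- mode == "train"
    if (is.null(state)) state <- classifierInitState(ncol(params[["clf.A2"]]))
    n <- nrow(C)
    pre1 <- C %*% params[["clf.A1"]] + rep(params[["clf.c1"]], each = n)
    L1 <- relu(pre1)
    bn1 <- bnForward(L1, params[["clf.g1"]], params[["clf.b1"]],
                     state$bn1, train)
    pre2 <- bn1$y %*% params[["clf.A2"]] + rep(params[["clf.c2"]], each = n)
    L2 <- relu(pre2)
    bn2 <- bnForward(L2, params[["clf.g2"]], params[["clf.b2"]],
                     state$bn2, train)
    logits <- bn2$y %*% params[["clf.A3"]] + rep(params[["clf.c3"]], each = n)
    Y <- softmaxRows(logits)
    state$bn1 <- bn1$state; state$bn2 <- bn2$state
    out <- list(Y = Y, state = state)
    if (cache)
        out$cache <- list(C = C, pre1 = pre1, bn1 = bn1, pre2 = pre2,
                          bn2 = bn2, Y = Y)
    out
}

#' @rdname classify
#' @param d classifier hidden width.
#' @export
classifierInitState <- function(d) {
    list(bn1 = bnInitState(d), bn2 = bnInitState(d))
}

# backward through the classifier head given dLogits (n x 2)
classifyBackward <- function(dLogits, cc, params) {
    n <- nrow(dLogits)
    grads <- list()
    grads[["clf.A3"]] <- crossprod(cc$bn2$y, dLogits)
    grads[["clf.c3"]] <- colSums(dLogits)
    dL2n <- tcrossprod(dLogits, params[["clf.A3"]])
    b2 <- bnBackward(dL2n, cc$bn2, params[["clf.g2"]])
    grads[["clf.g2"]] <- b2$dgamma; grads[["clf.b2"]] <- b2$dbeta
    dPre2 <- b2$dx * (cc$pre2 > 0)
    grads[["clf.A2"]] <- crossprod(cc$bn1$y, dPre2)
    grads[["clf.c2"]] <- colSums(dPre2)
    dL1n <- tcrossprod(dPre2, params[["clf.A2"]])
    b1 <- bnBackward(dL1n, cc$bn1, params[["clf.g1"]])
    grads[["clf.g1"]] <- b1$dgamma; grads[["clf.b1"]] <- b1$dbeta
    dPre1 <- b1$dx * (cc$pre1 > 0)
    grads[["clf.A1"]] <- crossprod(cc$C, dPre1)
    grads[["clf.c1"]] <- colSums(dPre1)
    grads$dC <- tcrossprod(dPre1, params[["clf.A1"]])
    grads
}
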