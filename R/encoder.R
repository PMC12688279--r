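#' Symmetric adjacency normalization with self-loops
#'
#' Returns `D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal row-sum
#' degree matrix of `A + I`.  Rows of isolated nodes reduce to the unit
#' self-loop entry.
#'
#' @param A square non-negative adjacency matrix.
#' @return normalized matrix of the same dimension.
#' @examples
#' normalizeAdjacency(matrix(0, 1, 1))            # [[1]]
#' normalizeAdjacency(matrix(c(0, 1, 1, 0), 2))   # all entries 0.5
#' @export
normalizeAdjacency <- function(A) {
    if (nrow(A) != ncol(A))
        stopTyped("shapeError", "adjacency must be square")
    if (any(A < 0))
        stopTyped("domainError", "adjacency entries must be non-negative")
    At <- A
    diag(At) <- diag(At) + 1
    dInv <- 1 / sqrt(rowSums(At))
    At * outer(dInv, dInv)
}

#' One graph-convolution layer
#'
#' `H = ReLU(A_norm %*% X %*% W)`: neighbourhood aggregation through the
#' symmetrically normalized self-looped adjacency followed by a linear map
#' and ReLU.
#'
#' @param X node feature matrix.
#' @param Anorm output of [normalizeAdjacency()].
#' @param W weight matrix.
#' @return activated node representation.
#' @export
gcnLayer <- function(X, Anorm, W) {
    if (ncol(Anorm) != nrow(X) || ncol(X) != nrow(W))
        stopTyped("shapeError", "incompatible dimensions in gcnLayer")
    relu(Anorm %*% X %*% W)
}

.LEAKY_SLOPE <- 0.2

leakyRelu <- function(x) ifelse(x > 0, x, .LEAKY_SLOPE * x)

#' Inter-view attention fusion
#'
#' For each target view `v`, scores every source view `u` by the
#' mean-pooled per-node score `LeakyReLU(a' [H(v)_i || H(u)_i])`,
#' normalizes scores across `u` with a softmax, and outputs
#' `H_attn(v) = ReLU(sum_u alpha_vu H(u))`.  Every attention weight row
#' lies on the simplex.
#'
#' @param Hlist list of per-view node representations (equal dims).
#' @param a attention parameter vector of length `2 * ncol(H)`.
#' @return list with `Hattn` (list of fused per-view outputs) and
#'   `weights` (V x V attention matrix, rows summing to 1).
#' @export
viewAttention <- function(Hlist, a) {
    V <- length(Hlist)
    if (V < 1L) stopTyped("shapeError", "need at least one view")
    d <- ncol(Hlist[[1L]])
    if (length(a) != 2L * d)
        stopTyped("shapeError", "attention vector must have length 2*dim")
    fw <- .viewAttentionForward(Hlist, a, useGat = TRUE)
    list(Hattn = fw$Hattn, weights = fw$alpha)
}

.viewAttentionForward <- function(Hlist, a, useGat = TRUE) {
    V <- length(Hlist)
    n <- nrow(Hlist[[1L]])
    d <- ncol(Hlist[[1L]])
    if (useGat) {
        a1 <- a[seq_len(d)]; a2 <- a[d + seq_len(d)]
        sv <- vapply(Hlist, function(H) as.numeric(H %*% a1),
                     numeric(n))          # n x V
        su <- vapply(Hlist, function(H) as.numeric(H %*% a2),
                     numeric(n))
        E <- matrix(0, V, V)
        slopes <- vector("list", V * V)
        for (v in seq_len(V)) for (u in seq_len(V)) {
            z <- sv[, v] + su[, u]
            E[v, u] <- mean(leakyRelu(z))
            slopes[[(v - 1L) * V + u]] <- ifelse(z > 0, 1, .LEAKY_SLOPE)
        }
        alpha <- softmaxRows(E)
    } else {
        alpha <- matrix(1 / V, V, V)
        slopes <- NULL
    }
    Spre <- lapply(seq_len(V), function(v) {
        S <- matrix(0, n, d)
        for (u in seq_len(V)) S <- S + alpha[v, u] * Hlist[[u]]
        S
    })
    Hattn <- lapply(Spre, relu)
    list(Hattn = Hattn, alpha = alpha, Spre = Spre, slopes = slopes)
}

# Full encoder forward pass over one (possibly masked) graph.
# Returns Z, the inter-view attention weights, and a cache for backward.
encoderForward <- function(viewMats, X, params, config, train = FALSE) {
    L <- config@encoder$layers
    p <- if (train) config@encoder$dropout else 0
    useGcn <- config@ablation$useGcn
    V <- length(viewMats)
    n <- nrow(X)
    if (n == 0L) stopTyped("preconditionError", "graph has zero nodes")
    vc <- vector("list", V)
    Hlist <- vector("list", V)
    for (v in seq_len(V)) {
        Anorm <- if (useGcn) normalizeAdjacency(viewMats[[v]]) else NULL
        H <- X
        Qs <- vector("list", L); masks <- vector("list", L)
        drops <- vector("list", L); Hs <- vector("list", L + 1L)
        Hs[[1L]] <- H
        for (l in seq_len(L)) {
            W <- params[[sprintf("enc.W.%d.%d", v, l)]]
            Q <- if (useGcn) Anorm %*% H else H
            pre <- Q %*% W
            H <- relu(pre)
            msk <- pre > 0
            dm <- if (p > 0) dropoutMask(nrow(H), ncol(H), p) else NULL
            if (!is.null(dm)) H <- H * dm
            Qs[[l]] <- Q; masks[[l]] <- msk; drops[l] <- list(dm)
            Hs[[l + 1L]] <- H
        }
        vc[[v]] <- list(Anorm = Anorm, Qs = Qs, masks = masks,
                        drops = drops, Hs = Hs)
        Hlist[[v]] <- H
    }
    at <- .viewAttentionForward(Hlist, params[["enc.a"]],
                                useGat = config@ablation$useGat)
    Hcat <- do.call(cbind, at$Hattn)
    # final integration is linear: a saturating/rectifying output here
    # produces dead zero-norm embeddings that break L2-normalized InfoNCE
    Z <- Hcat %*% params[["enc.Wg"]]
    list(Z = Z, attn = at$alpha,
         cache = list(viewCaches = vc, Hlist = Hlist, at = at,
                      Hcat = Hcat, V = V))
}

encoderBackward <- function(dZ, cache, params, config) {
    L <- config@encoder$layers
    p <- config@encoder$dropout
    useGcn <- config@ablation$useGcn
    useGat <- config@ablation$useGat
    V <- cache$V
    grads <- list()
    grads[["enc.Wg"]] <- crossprod(cache$Hcat, dZ)
    dHcat <- tcrossprod(dZ, params[["enc.Wg"]])
    d <- ncol(cache$Hlist[[1L]])
    n <- nrow(cache$Hlist[[1L]])
    at <- cache$at
    dHattn <- lapply(seq_len(V), function(v)
        dHcat[, (v - 1L) * d + seq_len(d), drop = FALSE])
    dH <- lapply(seq_len(V), function(v) matrix(0, n, d))
    da <- numeric(2L * d)
    dAlpha <- matrix(0, V, V)
    for (v in seq_len(V)) {
        dS <- dHattn[[v]] * (at$Spre[[v]] > 0)
        for (u in seq_len(V)) {
            dAlpha[v, u] <- sum(dS * cache$Hlist[[u]])
            dH[[u]] <- dH[[u]] + at$alpha[v, u] * dS
        }
    }
    if (useGat) {
        a1 <- params[["enc.a"]][seq_len(d)]
        a2 <- params[["enc.a"]][d + seq_len(d)]
        # softmax backward per target view, then mean-pooled score terms
        for (v in seq_len(V)) {
            al <- at$alpha[v, ]
            dE <- al * (dAlpha[v, ] - sum(al * dAlpha[v, ]))
            for (u in seq_len(V)) {
                if (dE[u] == 0) next
                dz <- dE[u] * at$slopes[[(v - 1L) * V + u]] / n
                da[seq_len(d)] <- da[seq_len(d)] +
                    as.numeric(crossprod(cache$Hlist[[v]], dz))
                da[d + seq_len(d)] <- da[d + seq_len(d)] +
                    as.numeric(crossprod(cache$Hlist[[u]], dz))
                dH[[v]] <- dH[[v]] + dz %o% a1
                dH[[u]] <- dH[[u]] + dz %o% a2
            }
        }
        grads[["enc.a"]] <- da
    }
    for (v in seq_len(V)) {
        vc <- cache$viewCaches[[v]]
        dcur <- dH[[v]]
        for (l in rev(seq_len(L))) {
            if (!is.null(vc$drops[[l]])) dcur <- dcur * vc$drops[[l]]
            dPre <- dcur * vc$masks[[l]]
            grads[[sprintf("enc.W.%d.%d", v, l)]] <-
                crossprod(vc$Qs[[l]], dPre)
            if (l > 1L) {
                W <- params[[sprintf("enc.W.%d.%d", v, l)]]
                dQ <- tcrossprod(dPre, W)
                dcur <- if (useGcn) vc$Anorm %*% dQ else dQ
            }
        }
    }
    grads
}

#' Encode a graph or masked view into node embeddings
#'
#' Runs the shared-weight multi-view encoder: a per-view GCN stack over
#' the three adjacency views (circRNA similarity, drug similarity,
#' association) with the block-diagonal joint feature matrix, inter-view
#' attention fusion, and a global linear integration layer.  The same
#' parameter object encodes any number of views (weight sharing).
#'
#' @param x a [HeterogeneousGraph] or [MaskedView].
#' @param params parameter list from [initModelParams()].
#' @param config a [ModelConfig].
#' @param train logical; enables dropout.
#' @return list with `Z` (node embedding matrix, circRNAs first),
#'   `attn` (inter-view attention weight matrix, rows sum to 1).
#' @export
encodeGraph <- function(x, params, config = modelConfig(),
                        train = FALSE) {
    g <- if (is(x, "MaskedView")) x@graph else x
    X <- blockDiag(g@Xc, g@Xd)
    fw <- encoderForward(g@views, X, params, config, train = train)
    list(Z = fw$Z, attn = fw$attn)
}

#' Initialize all trainable parameters
#'
#' Glorot-uniform initialization for every weight matrix and the
#' attention vector; unit/zero initialization for the batch-norm affine
#' parameters.  Deterministic for a fixed seed.
#'
#' @param nNodes number of graph nodes (M + N); the GCN input dimension.
#' @param config a [ModelConfig].
#' @param seed RNG seed (defaults to `train.seed`).
#' @return named list of parameters (flat, `enc.*`, `afc.*`, `clf.*`).
#' @export
initModelParams <- function(nNodes, config = modelConfig(),
                            seed = config@train$seed) {
    h <- config@encoder$hiddenDim
    L <- config@encoder$layers
    d <- config@afc$dim
    V <- 3L
    pairDim <- if (config@afc$pairFeatures == "concat") 2L * h else h
    clfIn <- if (config@ablation$useAfc) d else 2L * pairDim
    withSeed(seed, {
        params <- list()
        for (v in seq_len(V)) for (l in seq_len(L)) {
            fin <- if (l == 1L) nNodes else h
            params[[sprintf("enc.W.%d.%d", v, l)]] <- glorot(fin, h)
        }
        params[["enc.a"]] <- as.numeric(glorot(2L * h, 1L))
        params[["enc.Wg"]] <- glorot(V * h, h)
        if (config@ablation$useAfc) {
            params[["afc.Pu"]] <- glorot(pairDim, d)
            params[["afc.Ps"]] <- glorot(pairDim, d)
            params[["afc.Pt"]] <- glorot(pairDim, d)
            params[["afc.Po"]] <- glorot(d, d)
        }
        params[["clf.A1"]] <- glorot(clfIn, d)
        params[["clf.c1"]] <- numeric(d)
        params[["clf.g1"]] <- rep(1, d)
        params[["clf.b1"]] <- numeric(d)
        params[["clf.A2"]] <- glorot(d, d)
        params[["clf.c2"]] <- numeric(d)
        params[["clf.g2"]] <- rep(1, d)
        params[["clf.b2"]] <- numeric(d)
        params[["clf.A3"]] <- glorot(d, 2L)
        params[["clf.c3"]] <- numeric(2L)
        params
    })
}
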