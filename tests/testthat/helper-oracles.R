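# Independent brute-force oracles used to validate the implementation.
# These are deliberately naive (loops, quadratic DP) and share no code
# with the package internals.

# full dynamic-programming Levenshtein distance (unit costs)
dpLevenshtein <- function(a, b) {
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    n <- length(x); m <- length(y)
    D <- matrix(0L, n + 1L, m + 1L)
    D[, 1L] <- 0:n
    D[1L, ] <- 0:m
    for (i in seq_len(n)) for (j in seq_len(m))
        D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L,
                                 D[i, j] + (x[i] != y[j]))
    D[n + 1L, m + 1L]
}

# elementwise D^-1/2 (A+I) D^-1/2
naiveNormalizeAdjacency <- function(A) {
    At <- A + diag(nrow(A))
    d <- rowSums(At)
    out <- At
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
        out[i, j] <- At[i, j] / sqrt(d[i] * d[j])
    out
}

# per-anchor double-loop InfoNCE, both directions, L2-normalized inputs
naiveContrastive <- function(Z1, Z2, tau, inclPositive = TRUE) {
    nrm <- function(M) M / sqrt(rowSums(M^2))
    Z1 <- nrm(Z1); Z2 <- nrm(Z2)
    n <- nrow(Z1)
    dir <- function(A, B) {
        tot <- 0
        for (i in seq_len(n)) {
            num <- exp(sum(A[i, ] * B[i, ]) / tau)
            den <- 0
            for (k in seq_len(n)) {
                if (!inclPositive && k == i) next
                den <- den + exp(sum(A[i, ] * B[k, ]) / tau)
            }
            tot <- tot - log(num / den)
        }
        tot / n
    }
    (dir(Z1, Z2) + dir(Z2, Z1)) / 2
}

# naive per-head loop multi-head attention fusion, batch scope
naiveAttentionFuseBatch <- function(Fc, Fd, params, heads) {
    U <- Fc %*% params[["afc.Pu"]]
    S <- Fd %*% params[["afc.Ps"]]
    Tm <- Fd %*% params[["afc.Pt"]]
    d <- ncol(U); dh <- d / heads; n <- nrow(U)
    O <- NULL
    for (h in seq_len(heads)) {
        idx <- (h - 1) * dh + seq_len(dh)
        Oi <- matrix(0, n, dh)
        for (i in seq_len(n)) {
            logit <- sapply(seq_len(n), function(j)
                sum(U[i, idx] * S[j, idx]) / sqrt(dh))
            w <- exp(logit - max(logit)); w <- w / sum(w)
            for (j in seq_len(n)) Oi[i, ] <- Oi[i, ] + w[j] * Tm[j, idx]
        }
        O <- cbind(O, Oi)
    }
    O %*% params[["afc.Po"]]
}

# naive per-sample chunk-attention fusion, per-pair scope
naiveAttentionFusePair <- function(Fc, Fd, params, heads) {
    U <- Fc %*% params[["afc.Pu"]]
    S <- Fd %*% params[["afc.Ps"]]
    Tm <- Fd %*% params[["afc.Pt"]]
    d <- ncol(U); dh <- d / heads; n <- nrow(U)
    O <- matrix(0, n, d)
    for (p in seq_len(n)) {
        Uc <- matrix(U[p, ], heads, dh, byrow = TRUE)
        Sc <- matrix(S[p, ], heads, dh, byrow = TRUE)
        Tc <- matrix(Tm[p, ], heads, dh, byrow = TRUE)
        for (i in seq_len(heads)) {
            logit <- sapply(seq_len(heads), function(j)
                sum(Uc[i, ] * Sc[j, ]) / sqrt(dh))
            w <- exp(logit - max(logit)); w <- w / sum(w)
            acc <- rep(0, dh)
            for (j in seq_len(heads)) acc <- acc + w[j] * Tc[j, ]
            O[p, (i - 1) * dh + seq_len(dh)] <- acc
        }
    }
    O %*% params[["afc.Po"]]
}

# O(n^2) pairwise-comparison AUC with tie correction
naiveAUC <- function(scores, labels) {
    posIdx <- which(labels == 1); negIdx <- which(labels == 0)
    tot <- 0
    for (i in posIdx) for (j in negIdx)
        tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    tot / (length(posIdx) * length(negIdx))
}

# threshold-sweep AUPR (step integration), independent of the package
naiveAUPR <- function(scores, labels) {
    ths <- sort(unique(scores), decreasing = TRUE)
    nPos <- sum(labels == 1)
    prevRec <- 0; area <- 0
    for (t in ths) {
        sel <- scores >= t
        tp <- sum(labels[sel] == 1)
        prec <- tp / sum(sel)
        rec <- tp / nPos
        area <- area + (rec - prevRec) * prec
        prevRec <- rec
    }
    area
}
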