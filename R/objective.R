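#' Linearly annealed contrastive temperature
#'
#' `tau(t) = tauMax - (t/T) * (tauMax - tauMin)`, clamped to
#' `[tauMin, tauMax]`.  High early temperatures smooth the contrastive
#' loss landscape (exploration); the linear decay sharpens discrimination
#' towards the end of training.
#'
#' @param t training epoch index, `0 <= t <= T`.
#' @param tauMax,tauMin temperature endpoints, `tauMax >= tauMin > 0`.
#' @param T total number of epochs.
#' @return the temperature at epoch `t`.
#' @examples
#' temperatureAt(50, tauMax = 1, tauMin = 0.1, T = 100)  # 0.55
#' @export
temperatureAt <- function(t, tauMax = 1, tauMin = 0.1, T = 300L) {
    if (t < 0 || t > T)
        stopTyped("rangeError", "t must lie in [0, T]")
    if (!(tauMax >= tauMin && tauMin > 0))
        stopTyped("rangeError", "need tauMax >= tauMin > 0")
    min(tauMax, max(tauMin, tauMax - (t / T) * (tauMax - tauMin)))
}

#' InfoNCE contrastive loss between two view embeddings
#'
#' Embeddings are L2-normalized row-wise; the positive pair for node `i`
#' is its embedding in the other view, negatives are all other nodes'
#' embeddings in the other view.  Both anchoring directions are averaged.
#' By default the positive term is included in the denominator (standard
#' InfoNCE), so the loss is bounded below by 0 and the uniform-similarity
#' case equals `log(K + 1)` for `K` negatives; `"negatives_only"`
#' restricts the denominator to the negatives.
#'
#' @param Z1,Z2 aligned node embedding matrices from the two views.
#' @param tau temperature, `> 0`.
#' @param denominator `"incl_positive"` or `"negatives_only"`.
#' @param grad if TRUE also return gradients with respect to `Z1`, `Z2`.
#' @return the scalar loss, or (with `grad = TRUE`) a list
#'   `loss, dZ1, dZ2`.
#' @export
contrastiveLoss <- function(Z1, Z2, tau,
                            denominator = c("incl_positive",
                                            "negatives_only"),
                            grad = FALSE) {
    denominator <- match.arg(denominator)
    if (tau <= 0) stopTyped("domainError", "tau must be > 0")
    if (!all(is.finite(Z1)) || !all(is.finite(Z2)))
        stopTyped("domainError", "embeddings must be finite")
    if (!identical(dim(Z1), dim(Z2)))
        stopTyped("shapeError", "Z1 and Z2 must have identical shape")
    n <- nrow(Z1)
    if (n < 2L)
        stopTyped("preconditionError", "need at least one negative (n >= 2)")
    n1 <- sqrt(rowSums(Z1^2)); n2 <- sqrt(rowSums(Z2^2))
    if (any(n1 == 0) || any(n2 == 0))
        stopTyped("normalizationError",
                  "zero-norm embedding cannot be L2-normalized")
    Zh1 <- Z1 / n1
    Zh2 <- Z2 / n2
    S <- tcrossprod(Zh1, Zh2) / tau
    diagS <- diag(S)
    if (denominator == "incl_positive") {
        lse1 <- logSumExpRows(S)
        lse2 <- logSumExpRows(t(S))
        loss <- mean((lse1 - diagS) + (lse2 - diagS)) / 2
        if (!grad) return(loss)
        P1 <- softmaxRows(S)
        P2 <- t(softmaxRows(t(S)))
        dS <- (P1 + P2) / (2 * n)
        diag(dS) <- diag(dS) - 1 / n
    } else {
        Soff <- S; diag(Soff) <- -Inf
        lse1 <- logSumExpRows(Soff)
        lse2 <- logSumExpRows(t(Soff))
        loss <- mean((lse1 - diagS) + (lse2 - diagS)) / 2
        if (!grad) return(loss)
        P1 <- softmaxRows(Soff)
        P2 <- t(softmaxRows(t(Soff)))
        dS <- (P1 + P2) / (2 * n)
        diag(dS) <- -1 / n
    }
    dZh1 <- (dS %*% Zh2) / tau
    dZh2 <- (crossprod(dS, Zh1)) / tau
    dZ1 <- (dZh1 - Zh1 * rowSums(Zh1 * dZh1)) / n1
    dZ2 <- (dZh2 - Zh2 * rowSums(Zh2 * dZh2)) / n2
    list(loss = loss, dZ1 = dZ1, dZ2 = dZ2)
}

#' Combined training objective
#'
#' `L = L_supervised + lambdaC * L_contrastive`, the cross-entropy of the
#' classifier plus the weighted contrastive term.
#'
#' @param supervised supervised (cross-entropy) loss value.
#' @param contrastive contrastive loss value.
#' @param lambdaC non-negative contrastive weight.
#' @return the combined loss.
#' @export
totalLoss <- function(supervised, contrastive, lambdaC) {
    if (lambdaC < 0)
        stopTyped("rangeError", "lambdaC must be >= 0")
    supervised + lambdaC * contrastive
}
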