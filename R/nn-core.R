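# Internal neural-network primitives: Glorot initialization, row softmax,
# batch normalization (train/eval), dropout, and the Adam optimizer.
# Gradients throughout the package are hand-derived and verified against
# finite differences in the test suite.

glorot <- function(fanIn, fanOut, n = fanIn * fanOut) {
    r <- sqrt(6 / (fanIn + fanOut))
    matrix(stats::runif(n, -r, r), fanIn, fanOut)
}

relu <- function(x) (x > 0) * x

# row maxima via max.col (C implementation); -Inf entries are tolerated
rowMax <- function(X) {
    X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]
}

softmaxRows <- function(X) {
    E <- exp(X - rowMax(X))
    E / rowSums(E)
}

logSumExpRows <- function(X) {
    m <- rowMax(X)
    m + log(rowSums(exp(X - m)))
}

# -- batch normalization ---------------------------------------------------

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

bnForward <- function(x, gamma, beta, state, train) {
    n <- nrow(x)
    if (train) {
        if (n < 2L)
            stopTyped("degenerateBatchError",
                      "batch normalization requires n >= 2 in train mode")
        mu <- colMeans(x)
        xc <- x - rep(mu, each = n)
        v <- colMeans(xc^2)
        invStd <- 1 / sqrt(v + .BN_EPS)
        xhat <- xc * rep(invStd, each = n)
        state$mean <- .BN_MOMENTUM * state$mean + (1 - .BN_MOMENTUM) * mu
        state$var <- .BN_MOMENTUM * state$var + (1 - .BN_MOMENTUM) * v
    } else {
        invStd <- 1 / sqrt(state$var + .BN_EPS)
        xhat <- (x - rep(state$mean, each = n)) * rep(invStd, each = n)
    }
    y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
    list(y = y, xhat = xhat, invStd = invStd, state = state)
}

bnBackward <- function(dy, cache, gamma) {
    n <- nrow(dy)
    xhat <- cache$xhat
    dgamma <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    dxhat <- dy * rep(gamma, each = n)
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
           xhat * rep(colMeans(dxhat * xhat), each = n)) *
          rep(cache$invStd, each = n)
    list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bnInitState <- function(d) list(mean = rep(0, d), var = rep(1, d))

# -- dropout ---------------------------------------------------------------

dropoutMask <- function(n, d, rate) {
    if (rate <= 0) return(NULL)
    matrix(stats::rbinom(n * d, 1L, 1 - rate) / (1 - rate), n, d)
}

# -- Adam ------------------------------------------------------------------

adamInit <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0),
         t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
    state$t <- state$t + 1L
    c1 <- 1 - beta1^state$t
    c2 <- 1 - beta2^state$t
    for (nm in names(params)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] -
            lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    }
    list(params = params, state = state)
}
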