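mkAfcParams <- function(din = 6L, d = 8L, seed = 21L) {
    cfg <- modelConfig(afc.dim = d, afc.heads = 2L,
                       encoder.hiddenDim = din)
    initModelParams(10L, cfg, seed = seed)
}

test_that("attention fusion matches brute-force oracles in both scopes", {
    set.seed(22)
    p <- mkAfcParams()
    Fc <- matrix(rnorm(24), 4, 6)
    Fd <- matrix(rnorm(24), 4, 6)
    got <- attentionFuse(Fc, Fd, p, heads = 2L, scope = "batch")
    expect_equal(got$C, naiveAttentionFuseBatch(Fc, Fd, p, 2L),
                 tolerance = 1e-6)
    gotP <- attentionFuse(Fc, Fd, p, heads = 2L, scope = "per_pair")
    expect_equal(gotP$C, naiveAttentionFusePair(Fc, Fd, p, 2L),
                 tolerance = 1e-6)
})

test_that("attention weights are row-stochastic in every head and scope", {
    set.seed(23)
    p <- mkAfcParams()
    Fc <- matrix(rnorm(60), 10, 6)
    Fd <- matrix(rnorm(60), 10, 6)
    for (scope in c("batch", "per_pair")) {
        G <- attentionFuse(Fc, Fd, p, heads = 2L, scope = scope)$G
        for (Gi in G) expect_equal(rowSums(Gi), rep(1, nrow(Gi)),
                                   tolerance = 1e-12)
    }
})

test_that("single-sample batch scope reduces to the value projection", {
    p <- mkAfcParams()
    Fc <- matrix(rnorm(6), 1, 6)
    Fd <- matrix(rnorm(6), 1, 6)
    out <- attentionFuse(Fc, Fd, p, heads = 2L, scope = "batch")
    expect_equal(out$G[[1]], matrix(1, 1, 1))
    expect_equal(out$C, (Fd %*% p[["afc.Pt"]]) %*% p[["afc.Po"]])
})

test_that("batch-scope attention is uniform for constant logits", {
    p <- mkAfcParams()
    p[["afc.Pu"]] <- p[["afc.Pu"]] * 0      # zero queries -> 0 logits
    Fc <- matrix(rnorm(12), 2, 6)
    Fd <- matrix(rnorm(12), 2, 6)
    G <- attentionFuse(Fc, Fd, p, heads = 2L, scope = "batch")$G
    expect_equal(G[[1]], matrix(0.5, 2, 2))
})

test_that("fusion is equivariant to permuting the pair rows", {
    set.seed(24)
    p <- mkAfcParams()
    Fc <- matrix(rnorm(48), 8, 6)
    Fd <- matrix(rnorm(48), 8, 6)
    perm <- sample(8)
    for (scope in c("batch", "per_pair")) {
        C <- attentionFuse(Fc, Fd, p, 2L, scope = scope)$C
        Cp <- attentionFuse(Fc[perm, ], Fd[perm, ], p, 2L,
                            scope = scope)$C
        expect_equal(Cp, C[perm, ], tolerance = 1e-12)
    }
})

test_that("head count must divide the latent width", {
    p <- mkAfcParams(d = 8L)
    expect_error(attentionFuse(matrix(0, 2, 6), matrix(0, 2, 6), p,
                               heads = 3L), class = "configError")
})

test_that("classifier outputs a probability simplex and is deterministic", {
    set.seed(25)
    p <- mkAfcParams()
    Cm <- matrix(rnorm(40), 5, 8)
    st <- classifierInitState(8L)
    out <- classify(Cm, p, "train", st)
    expect_equal(rowSums(out$Y), rep(1, 5), tolerance = 1e-6)
    expect_true(all(out$Y > 0 & out$Y < 1))
    # eval with fixed stats: identical outputs on repeated calls
    e1 <- classify(Cm, p, "eval", out$state)
    e2 <- classify(Cm, p, "eval", out$state)
    expect_identical(e1$Y, e2$Y)
    # zero weights and biases give exactly (0.5, 0.5)
    p0 <- lapply(p, function(x) x * 0)
    expect_equal(classify(Cm, p0, "eval", st)$Y,
                 matrix(0.5, 5, 2))
    # degenerate single-row batch in train mode
    expect_error(classify(Cm[1, , drop = FALSE], p, "train", st),
                 class = "degenerateBatchError")
})

test_that("batch-norm running statistics track the training batches", {
    set.seed(26)
    p <- mkAfcParams()
    st <- classifierInitState(8L)
    Cm <- matrix(rnorm(400, mean = 3), 50, 8)
    for (i in 1:60) st <- classify(Cm, p, "train", st)$state
    pre1 <- Cm %*% p[["clf.A1"]]
    L1 <- pmax(pre1 + rep(p[["clf.c1"]], each = 50), 0)
    expect_equal(st$bn1$mean, colMeans(L1), tolerance = 0.01)
})
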