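test_that("adjacency normalization: closed forms and elementwise oracle", {
    expect_equal(normalizeAdjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
    expect_equal(normalizeAdjacency(matrix(c(0, 1, 1, 0), 2, 2)),
                 matrix(0.5, 2, 2))
    # isolated node keeps exactly its self-loop
    A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
    expect_equal(normalizeAdjacency(A)[3, ], c(0, 0, 1))
    set.seed(8)
    R <- matrix(runif(25), 5, 5); R <- (R + t(R)) / 2; diag(R) <- 0
    expect_equal(normalizeAdjacency(R), naiveNormalizeAdjacency(R),
                 tolerance = 1e-12)
    expect_error(normalizeAdjacency(-R), class = "domainError")
})

test_that("gcn layer: identity propagation, zero input, equivariance", {
    set.seed(3)
    X <- matrix(abs(rnorm(12)), 4, 3)
    expect_equal(gcnLayer(X, diag(4), diag(3)), X)
    expect_equal(gcnLayer(X * 0, diag(4), matrix(rnorm(9), 3)),
                 matrix(0, 4, 3))
    # permutation equivariance on a random 6-node graph
    A <- matrix(rbinom(36, 1, 0.4), 6); A <- pmax(A, t(A)); diag(A) <- 0
    An <- normalizeAdjacency(A)
    Xf <- matrix(rnorm(6 * 3), 6)
    W <- matrix(rnorm(9), 3)
    P <- diag(6)[sample(6), ]
    H <- gcnLayer(Xf, An, W)
    Hp <- gcnLayer(P %*% Xf, normalizeAdjacency(P %*% A %*% t(P)), W)
    expect_equal(Hp, P %*% H, tolerance = 1e-12)
})

test_that("inter-view attention weights live on the simplex", {
    set.seed(4)
    H1 <- matrix(rnorm(20), 5, 4)
    a <- rnorm(8)
    one <- viewAttention(list(H1), a)
    expect_equal(one$weights, matrix(1, 1, 1))
    expect_equal(one$Hattn[[1]], pmax(H1, 0))
    # identical views share the weight equally
    two <- viewAttention(list(H1, H1), a)
    expect_equal(two$weights, matrix(0.5, 2, 2))
    # random views: every row sums to one, weights non-negative
    H2 <- matrix(rnorm(20), 5, 4); H3 <- matrix(rnorm(20), 5, 4)
    w <- viewAttention(list(H1, H2, H3), a)$weights
    expect_equal(rowSums(w), rep(1, 3))
    expect_true(all(w >= 0))
})

test_that("inter-view attention scores match a hand softmax computation", {
    set.seed(6)
    Hlist <- lapply(1:3, function(i) matrix(rnorm(8), 4, 2))
    a <- rnorm(4)
    w <- viewAttention(Hlist, a)$weights
    lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
    for (v in 1:3) {
        e <- sapply(1:3, function(u)
            mean(lrelu(Hlist[[v]] %*% a[1:2] + Hlist[[u]] %*% a[3:4])))
        expect_equal(unname(w[v, ]), unname(exp(e) / sum(exp(e))),
                     tolerance = 1e-12)
    }
})

test_that("encoder output: weight sharing, determinism, masked-view identity", {
    g <- tinyGraph()
    cfg <- tinyConfig()
    n <- length(circIds(g)) + length(drugIds(g))
    params <- initModelParams(n, cfg, seed = 1L)
    # identical parameter object encodes both views (sharing contract)
    v1 <- maskPath(g, 0, seed = 1L)
    v2 <- maskEdge(g, 0, seed = 1L)
    z1 <- encodeGraph(v1, params, cfg)
    z2 <- encodeGraph(v2, params, cfg)
    # zero-intensity masks: identical embeddings elementwise
    expect_equal(z1$Z, z2$Z)
    # eval mode (dropout off) is bitwise reproducible
    expect_identical(encodeGraph(g, params, cfg)$Z,
                     encodeGraph(g, params, cfg)$Z)
    # attention rows on the simplex for every forward pass
    expect_equal(rowSums(z1$attn), rep(1, 3))
    # finite values with the default-size architecture
    cfgBig <- modelConfig()
    pBig <- initModelParams(n, cfgBig, seed = 2L)
    expect_true(all(is.finite(encodeGraph(g, pBig, cfgBig)$Z)))
})

test_that("full encoder is permutation-equivariant within entity types", {
    d <- tinyDataset()
    g <- tinyGraph(d)
    cfg <- tinyConfig()
    M <- length(circIds(g)); N <- length(drugIds(g))
    set.seed(7)
    pc <- sample(M)
    # permuting circRNAs permutes rows of A and the feature block;
    # encoder input dimension is node-indexed, so weights must be
    # permuted consistently for the comparison
    Ap <- AssociationMatrix(circIds(d$A)[pc], drugIds(d$A),
                            valuesMatrix(d$A)[pc, ])
    Xcp <- g@Xc[pc, pc]
    gp <- buildGraph(Xcp, g@Xd, Ap, 4L)
    params <- initModelParams(M + N, cfg, seed = 3L)
    perm <- c(pc, M + seq_len(N))
    paramsP <- params
    for (v in 1:3)
        paramsP[[sprintf("enc.W.%d.1", v)]] <-
            params[[sprintf("enc.W.%d.1", v)]][perm, , drop = FALSE]
    Z <- encodeGraph(g, params, cfg)$Z
    Zp <- encodeGraph(gp, paramsP, cfg)$Z
    expect_equal(Zp, Z[perm, ], tolerance = 1e-5)
})

test_that("ablation switches change the forward computation as specified", {
    g <- tinyGraph()
    n <- length(circIds(g)) + length(drugIds(g))
    cfgGat <- tinyConfig(ablation.useGat = FALSE)
    pGat <- initModelParams(n, cfgGat, seed = 4L)
    zGat <- encodeGraph(g, pGat, cfgGat)
    expect_equal(zGat$attn, matrix(1 / 3, 3, 3))   # uniform averaging
    cfgGcn <- tinyConfig(ablation.useGcn = FALSE)
    pGcn <- initModelParams(n, cfgGcn, seed = 4L)
    zGcn <- encodeGraph(g, pGcn, cfgGcn)
    expect_true(all(is.finite(zGcn$Z)))
    # without GCN the adjacency does not influence the embedding
    g2 <- maskEdge(g, 0.9, seed = 9L)
    expect_equal(encodeGraph(g2, pGcn, cfgGcn)$Z, zGcn$Z)
})
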