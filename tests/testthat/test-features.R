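test_that("sequence similarity matches the DP Levenshtein oracle exactly", {
    # fixed hand cases
    s <- SequenceSet(c("a", "b", "c", "d"),
                     c("ACGT", "ACGT", "AAAA", "CCCC"))
    S <- valuesMatrix(sequenceSimilarity(s))
    expect_equal(S["a", "b"], 1)                      # identical
    expect_equal(S["c", "d"], 0)                      # disjoint alphabets
    expect_equal(dpLevenshtein("ACGTACG", "TCGTTCG"), 2)
    s2 <- SequenceSet(c("x", "y"), c("ACGTACG", "TCGTTCG"))
    expect_equal(valuesMatrix(sequenceSimilarity(s2))["x", "y"], 1 - 2 / 7)
    # random pairs vs quadratic DP oracle, exact agreement
    set.seed(5)
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(1:10, function(i)
        paste(sample(bases, sample(5:25, 1), TRUE), collapse = ""),
        character(1))
    ss <- SequenceSet(sprintf("s%d", 1:10), seqs)
    S <- valuesMatrix(sequenceSimilarity(ss))
    for (k in 1:20) {
        ij <- sample(10, 2)
        d <- dpLevenshtein(seqs[ij[1]], seqs[ij[2]])
        expect_equal(S[ij[1], ij[2]],
                     1 - d / max(nchar(seqs[ij])), tolerance = 1e-12)
    }
    # empty sequences are rejected at the type boundary already
    expect_error(SequenceSet("a", ""), "non-empty")
})

test_that("GIP kernel: hand-computed 2x2 case, diagonal, identical profiles", {
    A <- AssociationMatrix(c("c1", "c2"), c("d1", "d2"), diag(2))
    g <- gipSimilarity(A, "circ")
    expect_equal(g$bandwidth@value, 1)                 # mean sq norm = 1
    expect_equal(valuesMatrix(g$sim)["c1", "c2"], exp(-2))
    expect_equal(diag(valuesMatrix(g$sim)), c(c1 = 1, c2 = 1))
    # identical rows give similarity exactly 1
    A2 <- AssociationMatrix(c("c1", "c2", "c3"), c("d1", "d2"),
                            matrix(c(1, 1, 0, 1, 1, 1), 3, 2))
    expect_equal(valuesMatrix(gipSimilarity(A2, "circ")$sim)["c1", "c2"], 1)
    expect_error(gipSimilarity(
        AssociationMatrix("c1", "d1", matrix(0, 1, 1)), "circ"),
        class = "undefinedBandwidthError")
})

test_that("GIP is equivariant under row+column permutation", {
    d <- tinyDataset()
    A <- d$A
    set.seed(9)
    pr <- sample(length(circIds(A))); pc <- sample(length(drugIds(A)))
    Ap <- AssociationMatrix(circIds(A)[pr], drugIds(A)[pc],
                            valuesMatrix(A)[pr, pc])
    S <- valuesMatrix(gipSimilarity(A, "circ")$sim)
    Sp <- valuesMatrix(gipSimilarity(Ap, "circ")$sim)
    expect_equal(unname(Sp), unname(S[pr, pr]), tolerance = 1e-12)
    Sd <- valuesMatrix(gipSimilarity(A, "drug")$sim)
    Sdp <- valuesMatrix(gipSimilarity(Ap, "drug")$sim)
    expect_equal(unname(Sdp), unname(Sd[pc, pc]), tolerance = 1e-12)
})

test_that("smaller GIP bandwidth raises every off-diagonal similarity", {
    d <- tinyDataset()
    P <- valuesMatrix(d$A)
    sq <- rowSums(P^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
    for (eta in c(2, 1, 0.5, 0.1)) {
        lo <- exp(-eta * D2); hi <- exp(-(eta / 2) * D2)
        off <- upper.tri(lo)
        expect_true(all(hi[off] >= lo[off]))
    }
    # the literal (non-inverted) bandwidth reading stays available
    g1 <- gipSimilarity(d$A, "drug", bandwidth = "inverse")
    g2 <- gipSimilarity(d$A, "drug", bandwidth = "literal")
    expect_equal(g2$bandwidth@value, 1 / g1$bandwidth@value)
})

test_that("Tanimoto similarity: hand cases and precondition", {
    fp <- FingerprintSet(c("a", "b", "c", "d"),
                         rbind(c(1, 0, 1, 1), c(0, 1, 1, 1),
                               c(1, 0, 1, 1), c(0, 1, 0, 0)))
    S <- valuesMatrix(tanimotoSimilarity(fp))
    expect_equal(S["a", "b"], 0.5)      # |I|=2, |U|=4
    expect_equal(S["a", "c"], 1)        # identical
    expect_equal(S["a", "d"], 0)        # disjoint
    expect_error(
        tanimotoSimilarity(FingerprintSet(c("a", "b"),
                                          rbind(c(1, 1), c(0, 0)))),
        class = "preconditionError")
})

test_that("similarity outputs satisfy the SimilarityMatrix invariants", {
    d <- tinyDataset()
    for (sim in list(sequenceSimilarity(d$seqs),
                     tanimotoSimilarity(d$fps),
                     gipSimilarity(d$A, "circ")$sim,
                     gipSimilarity(d$A, "drug")$sim)) {
        V <- valuesMatrix(sim)
        expect_lt(max(abs(V - t(V))), 1e-9)
        expect_true(all(V >= 0 & V <= 1))
        expect_equal(unname(diag(V)), rep(1, nrow(V)))
    }
})

test_that("conditional fusion averages only where both entities available", {
    d <- tinyDataset()
    gip <- gipSimilarity(d$A, "circ")$sim
    prim <- sequenceSimilarity(d$seqs)
    M <- length(ids(gip))
    # all available: plain average; identical inputs are a fixed point
    expect_equal(fuseSimilarities(gip, gip), valuesMatrix(gip),
                 ignore_attr = TRUE)
    Xall <- fuseSimilarities(prim, gip)
    expect_equal(unname(Xall),
                 unname((valuesMatrix(prim) + valuesMatrix(gip)) / 2))
    # none available: GIP alone
    Xnone <- fuseSimilarities(prim, gip, available = rep(FALSE, M))
    expect_equal(unname(Xnone), unname(valuesMatrix(gip)))
    # mixed: unavailable rows fall back to GIP
    av <- rep(c(TRUE, FALSE), length.out = M)
    Xmix <- fuseSimilarities(prim, gip, available = av)
    expect_equal(Xmix[!av, ], valuesMatrix(gip)[!av, ],
                 ignore_attr = TRUE)
    expect_equal(Xmix[av, av],
                 ((valuesMatrix(prim) + valuesMatrix(gip)) / 2)[av, av],
                 ignore_attr = TRUE)
    expect_equal(Xmix, t(Xmix))
    badIds <- SimilarityMatrix(rev(ids(gip)), valuesMatrix(gip), "gip")
    expect_error(fuseSimilarities(badIds, gip), class = "alignmentError")
})

test_that("graph assembly: association edges, k-NN sparsification, views", {
    d <- tinyDataset()
    g <- tinyGraph(d, knnK = 4L)
    e <- edges(g)
    M <- length(circIds(g)); N <- length(drugIds(g))
    # association edges are exactly the 1-entries of A
    cd <- e[e$type == "cd", ]
    expect_equal(nrow(cd), sum(valuesMatrix(d$A)))
    expect_true(all(valuesMatrix(d$A)[cbind(cd$i, cd$j - M)] == 1))
    expect_true(all(cd$w == 1))
    # no self edges; similarity weights in (0,1]
    expect_true(all(e$i < e$j))
    ws <- e$w[e$type != "cd"]
    expect_true(all(ws > 0 & ws <= 1))
    # views mirror the edge list symmetrically
    V <- graphViews(g)
    expect_equal(V$association[cbind(cd$i, cd$j)], cd$w)
    expect_equal(V$association, t(V$association))
    expect_equal(sum(V$circ_sim > 0), 2 * sum(e$type == "cc"))
    # A all-zero: only similarity edges (GIP needs an external A here)
    A0 <- AssociationMatrix(circIds(d$A), drugIds(d$A),
                            matrix(0, M, N))
    g0 <- buildGraph(g@Xc, g@Xd, A0, 4L)
    expect_equal(sum(edges(g0)$type == "cd"), 0L)
    # knnK = 0: association edges only
    gk0 <- buildGraph(g@Xc, g@Xd, d$A, 0L)
    expect_true(all(edges(gk0)$type == "cd"))
    # knnK >= n capped with a warning (per entity block)
    w <- capture_warnings(buildGraph(g@Xc, g@Xd, d$A, 1000L))
    expect_match(w, "capped", all = TRUE)
    expect_length(w, 2L)
})

test_that("mutual k-NN keeps an edge when either endpoint ranks the other", {
    # 3 circRNAs, sims c12=0.9 > c13=0.5 > c23=0.1, k=1:
    # node 1 picks 2; node 2 picks 1; node 3 picks 1 -> edges {1-2, 1-3}
    Xc <- matrix(c(1, 0.9, 0.5,
                   0.9, 1, 0.1,
                   0.5, 0.1, 1), 3, 3)
    A <- AssociationMatrix(c("c1", "c2", "c3"), "d1",
                           matrix(c(1, 0, 0), 3, 1))
    g <- suppressWarnings(buildGraph(Xc, matrix(1, 1, 1), A, 1L))
    cc <- edges(g)[edges(g)$type == "cc", ]
    expect_equal(nrow(cc), 2L)
    expect_setequal(paste(cc$i, cc$j), c("1 2", "1 3"))
    # brute-force union-of-top-k oracle on a random block
    d <- tinyDataset()
    gg <- tinyGraph(d, knnK = 3L)
    Xcc <- gg@Xc
    n <- nrow(Xcc)
    want <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        s <- Xcc[i, ]; s[i] <- -Inf
        top <- order(s, seq_len(n), decreasing = c(TRUE, FALSE),
                     method = "radix")[1:3]
        for (j in top) if (Xcc[i, j] > 0) {
            want[min(i, j), max(i, j)] <- TRUE
        }
    }
    got <- edges(gg)[edges(gg)$type == "cc", c("i", "j")]
    expect_equal(nrow(got), sum(want))
    expect_true(all(want[cbind(got$i, got$j)]))
})
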