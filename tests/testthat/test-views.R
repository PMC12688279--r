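test_that("edge mask removes exactly floor(beta*|E|) edges, replayable", {
    g <- tinyGraph()
    m <- nrow(edges(g))
    for (beta in c(0.1, 0.5, 0.9)) {
        v <- maskEdge(g, beta, seed = 11L)
        expect_length(removedEdges(v), floor(beta * m))
        expect_equal(nrow(edges(v)), m - floor(beta * m))
        # replay is bit-identical
        v2 <- maskEdge(g, beta, seed = 11L)
        expect_identical(removedEdges(v2), removedEdges(v))
    }
    # different seeds give different removed sets (collision check)
    sets <- lapply(1:10, function(s) removedEdges(maskEdge(g, 0.5, s)))
    expect_gt(length(unique(sets)), 8L)
})

test_that("zero-intensity masks are identities; beta=1 empties the graph", {
    g <- tinyGraph()
    v0 <- maskEdge(g, 0, seed = 1L)
    expect_length(removedEdges(v0), 0L)
    expect_identical(edges(v0), edges(g))
    expect_identical(graphViews(v0), graphViews(g))
    p0 <- maskPath(g, 0, seed = 1L)
    expect_identical(edges(p0), edges(g))
    v1 <- maskEdge(g, 1, seed = 1L)
    expect_equal(nrow(edges(v1)), 0L)
    expect_true(all(graphViews(v1)$association == 0))
})

test_that("path mask removes all edges incident to visited nodes", {
    # path graph a-b-c via a hand-built 3-node graph; a walk from b of
    # length 1 visits {b, a} or {b, c}: either way both edges vanish
    A <- AssociationMatrix(c("a", "c"), "b", matrix(c(1, 1), 2, 1))
    g <- suppressWarnings(
        buildGraph(diag(2), matrix(1, 1, 1), A, 0L))
    expect_equal(nrow(edges(g)), 2L)
    hit <- vapply(1:20, function(s) {
        v <- maskPath(g, alpha = 1 / 3, walkLen = 1L, seed = s)
        rem <- removedEdges(v)
        # whenever the start node is b (node 3), both edges must go
        if (3L %in% c(edges(g)$i[rem], edges(g)$j[rem]))
            length(rem) == 2L else NA
    }, logical(1))
    expect_true(all(hit[!is.na(hit)]))
    expect_true(any(!is.na(hit)))
})

test_that("alpha=1 with long walks removes every edge of a connected graph", {
    g <- tinyGraph()
    v <- maskPath(g, 1, walkLen = 30L, seed = 3L)
    expect_equal(nrow(edges(v)), 0L)
})

test_that("masking preserves node features and the vertex set", {
    g <- tinyGraph()
    for (v in list(maskPath(g, 0.4, 3L, 5L), maskEdge(g, 0.4, 5L))) {
        mg <- maskedGraph(v)
        expect_identical(mg@Xc, g@Xc)
        expect_identical(mg@Xd, g@Xd)
        expect_identical(circIds(mg), circIds(g))
        expect_identical(drugIds(mg), drugIds(g))
        expect_identical(dim(graphViews(v)$circ_sim),
                         dim(graphViews(g)$circ_sim))
        # removed edges zeroed in the views they appeared in
        rem <- edges(g)[removedEdges(v), ]
        for (r in seq_len(nrow(rem))) {
            view <- switch(rem$type[r], cc = "circ_sim", dd = "drug_sim",
                           cd = "association")
            expect_equal(graphViews(v)[[view]][rem$i[r], rem$j[r]], 0)
        }
    }
})

test_that("path mask removal count is non-decreasing in alpha on average", {
    g <- tinyGraph()
    meanRemoved <- vapply(c(0.1, 0.3, 0.6, 0.9), function(a)
        mean(vapply(1:50, function(s)
            length(removedEdges(maskPath(g, a, 3L, s))), numeric(1))),
        numeric(1))
    expect_true(all(diff(meanRemoved) >= 0))
})

test_that("mask intensity outside [0,1] and edgeless graphs are handled", {
    g <- tinyGraph()
    expect_error(maskEdge(g, -0.1), class = "rangeError")
    expect_error(maskPath(g, 1.2), class = "rangeError")
    A0 <- AssociationMatrix(c("a", "b"), "d", matrix(0, 2, 1))
    g0 <- buildGraph(diag(2) * 0 + diag(2), matrix(1, 1, 1), A0, 0L)
    expect_warning(v <- maskEdge(g0, 0.5), "no edges")
    expect_length(removedEdges(v), 0L)
})
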