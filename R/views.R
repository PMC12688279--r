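.identityView <- function(G, strategy, intensity, seed) {
    new("MaskedView", base = G, strategy = strategy,
        intensity = intensity, seed = as.integer(seed),
        removedEdges = integer(), graph = G)
}

# zero removed edges out of the edge table and every adjacency view
.maskedViewMats <- function(G, removed) {
    views <- G@views
    if (length(removed)) {
        e <- G@edges[removed, , drop = FALSE]
        for (tp in unique(e$type)) {
            v <- switch(tp, cc = "circ_sim", dd = "drug_sim",
                        cd = "association")
            sub <- e[e$type == tp, , drop = FALSE]
            idx <- rbind(cbind(sub$i, sub$j), cbind(sub$j, sub$i))
            views[[v]][idx] <- 0
        }
    }
    views
}

.applyMask <- function(G, strategy, intensity, seed, removed) {
    removed <- sort(unique(as.integer(removed)))
    g2 <- G
    if (length(removed)) {
        g2@views <- .maskedViewMats(G, removed)
        g2@edges <- G@edges[-removed, , drop = FALSE]
    }
    new("MaskedView", base = G, strategy = strategy,
        intensity = intensity, seed = as.integer(seed),
        removedEdges = removed, graph = g2)
}

# neighbour lists over all edge types (similarity and association)
.adjacencyList <- function(G) {
    n <- length(G@circIds) + length(G@drugIds)
    e <- G@edges
    adj <- rep(list(integer()), n)
    if (nrow(e)) {
        sp <- split(c(e$j, e$i), factor(c(e$i, e$j), levels = seq_len(n)))
        adj[as.integer(names(sp))] <- sp
    }
    adj
}

# sampling cores, shared by the exported maskers and the training loop
.samplePathRemoval <- function(G, alpha, walkLen, seed, adj = NULL) {
    n <- length(G@circIds) + length(G@drugIds)
    nStart <- ceiling(alpha * n)
    if (is.null(adj)) adj <- .adjacencyList(G)
    visited <- withSeed(seed, {
        starts <- sample.int(n, nStart)
        vis <- logical(n)
        for (s in starts) {
            cur <- s
            vis[cur] <- TRUE
            for (step in seq_len(walkLen)) {
                nb <- adj[[cur]]
                if (!length(nb)) break
                cur <- nb[sample.int(length(nb), 1L)]
                vis[cur] <- TRUE
            }
        }
        vis
    })
    which(visited[G@edges$i] | visited[G@edges$j])
}

.sampleEdgeRemoval <- function(G, beta, seed) {
    m <- nrow(G@edges)
    nRemove <- floor(beta * m)
    if (nRemove == 0L) return(integer())
    withSeed(seed, sample.int(m, nRemove))
}

#' Path-masked graph view
#'
#' Samples `ceiling(alpha * |V|)` start nodes uniformly without
#' replacement, performs a uniform random walk of `walkLen` steps from
#' each (walks may traverse any edge type), and removes every edge
#' incident to any visited node.  Node features and the vertex set are
#' untouched, so both masked views share one node index space for the
#' shared-weight encoder.  Deterministic for a fixed seed.
#'
#' @param G a [HeterogeneousGraph].
#' @param alpha masking intensity in `[0,1]` (fraction of nodes used as
#'   walk starts).
#' @param walkLen walk length in steps (>= 1).
#' @param seed integer RNG seed.
#' @return a [MaskedView] with strategy `"path"`.
#' @export
maskPath <- function(G, alpha, walkLen = 3L, seed = 42L) {
    assertScalarIn(alpha, 0, 1, "alpha")
    if (walkLen < 1L) stopTyped("rangeError", "walkLen must be >= 1")
    if (!nrow(G@edges)) {
        warning("graph has no edges; path mask is the identity")
        return(.identityView(G, "path", alpha, seed))
    }
    if (alpha == 0) return(.identityView(G, "path", alpha, seed))
    removed <- .samplePathRemoval(G, alpha, walkLen, seed)
    .applyMask(G, "path", alpha, seed, removed)
}

#' Edge-masked graph view
#'
#' Removes exactly `floor(beta * |E|)` edges sampled uniformly without
#' replacement; deterministic for a fixed seed.
#'
#' @param G a [HeterogeneousGraph].
#' @param beta masking intensity in `[0,1]`.
#' @param seed integer RNG seed.
#' @return a [MaskedView] with strategy `"edge"`.
#' @export
maskEdge <- function(G, beta, seed = 42L) {
    assertScalarIn(beta, 0, 1, "beta")
    m <- nrow(G@edges)
    if (!m) {
        warning("graph has no edges; edge mask is the identity")
        return(.identityView(G, "edge", beta, seed))
    }
    removed <- .sampleEdgeRemoval(G, beta, seed)
    if (!length(removed)) return(.identityView(G, "edge", beta, seed))
    .applyMask(G, "edge", beta, seed, removed)
}
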