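#' Cross-validation fold assignment over pairs
#'
#' Partitions the known positives of `A` into `k` near-equal disjoint
#' folds and samples `negRatio` negatives per positive uniformly from the
#' 0-entries, disjoint across folds.  Deterministic per seed.
#'
#' @param A an [AssociationMatrix].
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @param negRatio negatives sampled per positive.
#' @return data.frame with columns `i` (circ row), `j` (drug column),
#'   `label` and `fold`.
#' @export
makeFolds <- function(A, k, seed = 42L, negRatio = 1) {
    if (k < 2L) stopTyped("rangeError", "k must be >= 2")
    vals <- A@values
    pos <- which(vals == 1)
    if (length(pos) < k)
        stopTyped("preconditionError",
                  "need at least k positives to form k folds")
    zero <- which(vals == 0)
    withSeed(seed, {
        posPerm <- sample(pos)
        foldSizes <- rep(length(pos) %/% k, k) +
            (seq_len(k) <= length(pos) %% k)
        posFold <- rep(seq_len(k), foldSizes)
        negSizes <- floor(negRatio * foldSizes)
        if (sum(negSizes) > length(zero))
            stopTyped("preconditionError",
                      "not enough 0-entries to sample disjoint negatives")
        negPerm <- sample(zero, sum(negSizes))
        negFold <- rep(seq_len(k), negSizes)
        idx <- c(posPerm, negPerm)
        data.frame(i = (idx - 1L) %% nrow(vals) + 1L,
                   j = (idx - 1L) %/% nrow(vals) + 1L,
                   label = rep(c(1L, 0L), c(length(posPerm),
                                            length(negPerm))),
                   fold = c(posFold, negFold))
    })
}

# -- pair feature extraction ----------------------------------------------

.pairFeatures <- function(Z1, Z2, pairs, M, mode) {
    ci <- pairs$i; di <- M + pairs$j
    if (mode == "concat") {
        list(Fc = cbind(Z1[ci, , drop = FALSE], Z2[ci, , drop = FALSE]),
             Fd = cbind(Z1[di, , drop = FALSE], Z2[di, , drop = FALSE]))
    } else {
        Zb <- (Z1 + Z2) / 2
        list(Fc = Zb[ci, , drop = FALSE], Fd = Zb[di, , drop = FALSE])
    }
}

# contiguous batches of at least 2 rows (batch-norm needs n >= 2)
.batchIndices <- function(n, size) {
    if (n <= size) return(list(seq_len(n)))
    starts <- seq(1L, n, by = size)
    out <- lapply(starts, function(s) s:min(s + size - 1L, n))
    last <- length(out)
    if (length(out[[last]]) < 2L) {
        out[[last - 1L]] <- c(out[[last - 1L]], out[[last]])
        out[[last]] <- NULL
    }
    out
}

# supervised head: forward+backward over batches; returns loss, param
# grads and gradients w.r.t. the pair feature blocks
.supervisedPass <- function(Fc, Fd, labels, params, bnState, config,
                            train = TRUE) {
    n <- nrow(Fc)
    useAfc <- config@ablation$useAfc
    heads <- config@afc$heads
    batches <- .batchIndices(n, config@afc$batchSize)
    loss <- 0
    grads <- list()
    dFc <- matrix(0, n, ncol(Fc)); dFd <- matrix(0, n, ncol(Fd))
    addGrad <- function(g, nm, val) {
        g[[nm]] <- if (is.null(g[[nm]])) val else g[[nm]] + val
        g
    }
    for (b in batches) {
        nb <- length(b)
        if (useAfc) {
            af <- attentionFuse(Fc[b, , drop = FALSE],
                                Fd[b, , drop = FALSE], params, heads,
                                scope = config@afc$attentionScope,
                                cache = TRUE)
            C <- af$C
        } else {
            C <- cbind(Fc[b, , drop = FALSE], Fd[b, , drop = FALSE])
        }
        cf <- classify(C, params, if (train) "train" else "eval",
                       bnState, cache = TRUE)
        bnState <- cf$state
        lab <- labels[b]
        pr <- cf$Y[cbind(seq_len(nb), lab + 1L)]
        loss <- loss - sum(log(pmax(pr, 1e-300)))
        oneHot <- matrix(0, nb, 2L)
        oneHot[cbind(seq_len(nb), lab + 1L)] <- 1
        dLogits <- (cf$Y - oneHot) / n
        cb <- classifyBackward(dLogits, cf$cache, params)
        for (nm in grep("^clf\\.", names(cb), value = TRUE))
            grads <- addGrad(grads, nm, cb[[nm]])
        if (useAfc) {
            ab <- attentionFuseBackward(cb$dC, af$cache, params)
            for (nm in grep("^afc\\.", names(ab), value = TRUE))
                grads <- addGrad(grads, nm, ab[[nm]])
            dFc[b, ] <- ab$dFcirc
            dFd[b, ] <- ab$dFdrug
        } else {
            dFc[b, ] <- cb$dC[, seq_len(ncol(Fc)), drop = FALSE]
            dFd[b, ] <- cb$dC[, ncol(Fc) + seq_len(ncol(Fd)),
                              drop = FALSE]
        }
    }
    list(loss = loss / n, grads = grads, dFc = dFc, dFd = dFd,
         bnState = bnState)
}

# scatter pair-feature gradients back onto the two view embeddings
.pairFeaturesBackward <- function(dFc, dFd, pairs, M, mode, n, h) {
    ci <- pairs$i; di <- M + pairs$j
    scatter <- function(dMat, idx) {
        out <- matrix(0, n, ncol(dMat))
        agg <- rowsum(dMat, idx)
        out[as.integer(rownames(agg)), ] <- agg
        out
    }
    if (mode == "concat") {
        dZ1 <- scatter(dFc[, seq_len(h), drop = FALSE], ci) +
               scatter(dFd[, seq_len(h), drop = FALSE], di)
        dZ2 <- scatter(dFc[, h + seq_len(h), drop = FALSE], ci) +
               scatter(dFd[, h + seq_len(h), drop = FALSE], di)
    } else {
        dZb <- scatter(dFc, ci) + scatter(dFd, di)
        dZ1 <- dZb / 2
        dZ2 <- dZb / 2
    }
    list(dZ1 = dZ1, dZ2 = dZ2)
}

# training-loop mask resampling: same sampling cores as maskPath/maskEdge
# but only the zeroed adjacency views are materialized
.maskedViews <- function(graph, config, seed, epoch, adj) {
    abl <- config@ablation
    v1 <- if (abl$useMaskPath && config@mask$alpha > 0 &&
              nrow(graph@edges))
        .maskedViewMats(graph,
                        .samplePathRemoval(graph, config@mask$alpha,
                                           config@mask$walkLen,
                                           deriveSeed(seed, 2L * epoch),
                                           adj))
    else graph@views
    v2 <- if (abl$useMaskEdge && nrow(graph@edges))
        .maskedViewMats(graph,
                        .sampleEdgeRemoval(graph, config@mask$beta,
                                           deriveSeed(seed,
                                                      2L * epoch + 1L)))
    else graph@views
    list(v1 = v1, v2 = v2)
}

#' Train the dual-masked contrastive model
#'
#' Per epoch: resample the two masked views, encode both with the
#' shared-weight encoder, evaluate the InfoNCE loss at the annealed
#' temperature, build pair features, run the attention fusion classifier,
#' and take one Adam step on the combined objective
#' `L_supervised + lambdaC * L_contrastive`.
#'
#' @param graph a [HeterogeneousGraph] built from training data only.
#' @param pairs data.frame of training pairs with columns `i` (circRNA
#'   row index) and `j` (drug column index).
#' @param labels binary vector parallel to `pairs`.
#' @param config a [ModelConfig].
#' @return a `cdsgclModel`: list with trained `params`, batch-norm
#'   `bnState`, `config`, `dims`, and the per-epoch loss `trace`.
#' @export
trainModel <- function(graph, pairs, labels, config = modelConfig()) {
    if (!nrow(pairs))
        stopTyped("preconditionError", "training pairs must be non-empty")
    M <- length(graph@circIds); N <- length(graph@drugIds)
    nNodes <- M + N
    seed <- config@train$seed
    epochs <- config@train$epochs
    lossGroup <- config@loss
    params <- initModelParams(nNodes, config, seed)
    adam <- adamInit(params)
    bnState <- classifierInitState(ncol(params[["clf.A2"]]))
    X <- blockDiag(graph@Xc, graph@Xd)
    trace <- numeric(epochs)
    labels <- as.integer(labels)
    views <- NULL
    adj <- .adjacencyList(graph)
    withSeed(deriveSeed(seed, 7L), {
        for (epoch in seq_len(epochs)) {
            tau <- temperatureAt(epoch, lossGroup$tauMax,
                                 lossGroup$tauMin, epochs)
            if (is.null(views) || config@mask$resampleEachEpoch)
                views <- .maskedViews(graph, config, seed, epoch, adj)
            fw1 <- encoderForward(views$v1, X, params, config,
                                  train = TRUE)
            fw2 <- encoderForward(views$v2, X, params, config,
                                  train = TRUE)
            conLoss <- 0
            dZ1 <- matrix(0, nNodes, ncol(fw1$Z))
            dZ2 <- dZ1
            if (lossGroup$lambdaC > 0) {
                cl <- tryCatch(
                    contrastiveLoss(fw1$Z, fw2$Z, tau,
                                    lossGroup$denominator, grad = TRUE),
                    normalizationError = function(e)
                        stopTyped("divergenceError",
                                  "epoch %d: %s", epoch,
                                  conditionMessage(e)))
                conLoss <- cl$loss
                dZ1 <- lossGroup$lambdaC * cl$dZ1
                dZ2 <- lossGroup$lambdaC * cl$dZ2
            }
            pf <- .pairFeatures(fw1$Z, fw2$Z, pairs, M,
                                config@afc$pairFeatures)
            sp <- .supervisedPass(pf$Fc, pf$Fd, labels, params, bnState,
                                  config, train = TRUE)
            bnState <- sp$bnState
            pb <- .pairFeaturesBackward(sp$dFc, sp$dFd, pairs, M,
                                        config@afc$pairFeatures, nNodes,
                                        ncol(fw1$Z))
            dZ1 <- dZ1 + pb$dZ1
            dZ2 <- dZ2 + pb$dZ2
            g1 <- encoderBackward(dZ1, fw1$cache, params, config)
            g2 <- encoderBackward(dZ2, fw2$cache, params, config)
            grads <- sp$grads
            for (nm in names(g1))
                grads[[nm]] <- g1[[nm]] + g2[[nm]]
            total <- totalLoss(sp$loss, conLoss, lossGroup$lambdaC)
            if (!is.finite(total))
                stopTyped("divergenceError",
                          "non-finite loss at epoch %d", epoch)
            trace[epoch] <- total
            st <- adamStep(params, grads, adam, config@train$lr)
            params <- st$params
            adam <- st$state
        }
    })
    structure(list(params = params, bnState = bnState, config = config,
                   dims = list(M = M, N = N), trace = trace),
              class = "cdsgclModel")
}

#' @export
print.cdsgclModel <- function(x, ...) {
    cat(sprintf(
        "cdsgclModel: %d circRNAs + %d drugs, %d epochs, final loss %.4f\n",
        x$dims$M, x$dims$N, length(x$trace), x$trace[length(x$trace)]))
    invisible(x)
}

#' Score candidate pairs with a trained model
#'
#' Encodes the (unmasked) graph in eval mode and returns the positive
#' class probability for each requested pair.
#'
#' @param model a trained `cdsgclModel`.
#' @param graph the [HeterogeneousGraph] to encode.
#' @param pairs data.frame with circRNA row indices `i` and drug column
#'   indices `j`.
#' @return numeric score vector in `[0,1]`.
#' @export
scorePairs <- function(model, graph, pairs) {
    config <- model$config
    M <- length(graph@circIds)
    X <- blockDiag(graph@Xc, graph@Xd)
    fw <- encoderForward(graph@views, X, model$params, config,
                         train = FALSE)
    pf <- .pairFeatures(fw$Z, fw$Z, pairs, M, config@afc$pairFeatures)
    batches <- .batchIndices(nrow(pf$Fc), config@afc$batchSize)
    scores <- numeric(nrow(pf$Fc))
    for (b in batches) {
        C <- if (config@ablation$useAfc)
            attentionFuse(pf$Fc[b, , drop = FALSE],
                          pf$Fd[b, , drop = FALSE], model$params,
                          config@afc$heads,
                          scope = config@afc$attentionScope)$C
        else cbind(pf$Fc[b, , drop = FALSE], pf$Fd[b, , drop = FALSE])
        scores[b] <- classify(C, model$params, "eval",
                              model$bnState)$Y[, 2L]
    }
    scores
}

.alignPrimary <- function(sim, targetIds) {
    if (is.null(sim))
        return(list(values = NULL, avail = rep(FALSE, length(targetIds))))
    pos <- match(targetIds, sim@ids)
    avail <- !is.na(pos)
    n <- length(targetIds)
    vals <- matrix(0, n, n)
    if (any(avail))
        vals[avail, avail] <- sim@values[pos[avail], pos[avail]]
    diag(vals) <- 1
    list(values = vals, avail = avail)
}

# gipA: matrix the GIP kernels are computed from (training matrix unless
# the leaky audit variant is requested); Atrain: association edges
.foldFeatures <- function(Atrain, seqSimAligned, strSimAligned, config,
                          gipA = Atrain) {
    bw <- config@features$gipBandwidth
    gC <- gipSimilarity(gipA, "circ", bw)$sim
    gD <- gipSimilarity(gipA, "drug", bw)$sim
    primC <- SimilarityMatrix(Atrain@circIds,
                              seqSimAligned$values %||% diag(length(Atrain@circIds)),
                              "sequence")
    primD <- SimilarityMatrix(Atrain@drugIds,
                              strSimAligned$values %||% diag(length(Atrain@drugIds)),
                              "structure")
    Xc <- fuseSimilarities(primC, gC, seqSimAligned$avail)
    Xd <- fuseSimilarities(primD, gD, strSimAligned$avail)
    buildGraph(Xc, Xd, Atrain, config@features$knnK)
}

#' Fold-safe k-fold cross-validation
#'
#' For each fold the held-out positives are zeroed out of the association
#' matrix *before* GIP similarity and graph construction are recomputed
#' from the training matrix (asserted; reported in the `foldSafe` slot),
#' preventing test-label leakage through the features.  The model is
#' retrained per fold and evaluated on the held-out positives plus the
#' fold's sampled negatives.  Setting `features.leakyGip = TRUE`
#' reproduces the naive whole-matrix GIP variant for comparison.
#'
#' @param A an [AssociationMatrix].
#' @param seqs optional [SequenceSet] of circRNA host-gene sequences;
#'   circRNAs absent from it fall back to GIP-only features.
#' @param fps optional [FingerprintSet]; likewise for drugs.
#' @param config a [ModelConfig]; `cv.folds` selects 5- or 10-fold.
#' @return a [MetricsReport].
#' @export
crossValidate <- function(A, seqs = NULL, fps = NULL,
                          config = modelConfig()) {
    k <- config@cv$folds
    seed <- config@train$seed
    folds <- makeFolds(A, k, seed, config@train$negRatio)
    seqAl <- .alignPrimary(if (is.null(seqs)) NULL
                           else sequenceSimilarity(seqs), A@circIds)
    strAl <- .alignPrimary(if (is.null(fps)) NULL
                           else tanimotoSimilarity(fps), A@drugIds)
    perFold <- NULL
    foldSafe <- TRUE
    for (f in seq_len(k)) {
        test <- folds[folds$fold == f, , drop = FALSE]
        train <- folds[folds$fold != f, , drop = FALSE]
        Atr <- A@values
        testPosIdx <- cbind(test$i, test$j)[test$label == 1L, ,
                                            drop = FALSE]
        Atr[testPosIdx] <- 0
        if (any(Atr[cbind(test$i, test$j)] != 0)) foldSafe <- FALSE
        AtrObj <- AssociationMatrix(A@circIds, A@drugIds, Atr)
        graph <- .foldFeatures(AtrObj, seqAl, strAl, config,
                               gipA = if (config@features$leakyGip) A
                                      else AtrObj)
        model <- trainModel(graph, train[, c("i", "j")], train$label,
                            config)
        scores <- scorePairs(model, graph, test[, c("i", "j")])
        met <- computeMetrics(scores, test$label)
        perFold <- rbind(perFold, data.frame(fold = f, t(met)))
    }
    summaryVec <- colMeans(perFold[, -1L])
    new("MetricsReport", perFold = perFold,
        summary = summaryVec, folds = folds,
        config = c(configToList(config),
                   list(hash = configHash(config))),
        foldSafe = foldSafe)
}

#' Fit the model on the full association matrix
#'
#' Builds features and the heterogeneous graph from the complete matrix,
#' samples `negRatio` negatives per positive, and trains once; the
#' returned bundle feeds [rankCandidates()].
#'
#' @inheritParams crossValidate
#' @return list with `model` (a `cdsgclModel`), `graph` and `A`.
#' @export
fitModel <- function(A, seqs = NULL, fps = NULL, config = modelConfig()) {
    seed <- config@train$seed
    seqAl <- .alignPrimary(if (is.null(seqs)) NULL
                           else sequenceSimilarity(seqs), A@circIds)
    strAl <- .alignPrimary(if (is.null(fps)) NULL
                           else tanimotoSimilarity(fps), A@drugIds)
    graph <- .foldFeatures(A, seqAl, strAl, config)
    pos <- which(A@values == 1)
    zero <- which(A@values == 0)
    nNeg <- min(length(zero), floor(config@train$negRatio * length(pos)))
    neg <- withSeed(deriveSeed(seed, 13L), sample(zero, nNeg))
    idx <- c(pos, neg)
    pairs <- data.frame(i = (idx - 1L) %% nrow(A@values) + 1L,
                        j = (idx - 1L) %/% nrow(A@values) + 1L)
    labels <- rep(c(1L, 0L), c(length(pos), length(neg)))
    model <- trainModel(graph, pairs, labels, config)
    list(model = model, graph = graph, A = A)
}

#' Rank candidate circRNAs for one drug
#'
#' Scores every circRNA against the requested drug with the trained
#' model's positive-class probability, optionally excludes associations
#' already known in training, and returns the top `k` in descending score
#' order (ties broken by circRNA identifier).
#'
#' @param fit result of [fitModel()] (or a list with `model`, `graph`,
#'   `A`).
#' @param drugId drug identifier present in the association matrix.
#' @param k table length (capped at the number of candidates, with a
#'   warning).
#' @param excludeKnown drop circRNAs already associated in training.
#' @return a [RankingTable].
#' @export
rankCandidates <- function(fit, drugId, k = 20L, excludeKnown = TRUE) {
    A <- fit$A
    j <- match(drugId, A@drugIds)
    if (is.na(j))
        stopTyped("lookupError", "unknown drug id '%s'", drugId)
    cand <- seq_along(A@circIds)
    if (excludeKnown) cand <- cand[A@values[, j] == 0]
    if (!length(cand))
        stopTyped("preconditionError", "no candidate circRNAs left")
    pairs <- data.frame(i = cand, j = j)
    sc <- scorePairs(fit$model, fit$graph, pairs)
    if (k > length(cand)) {
        warning(sprintf("k = %d exceeds %d candidates; returning all",
                        k, length(cand)))
        k <- length(cand)
    }
    ord <- order(sc, A@circIds[cand], decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(k)]
    RankingTable(drugId, A@circIds[cand][ord], sc[ord])
}

#' Permute association labels (negative control)
#'
#' Randomly permutes the 0/1 entries of the association matrix over all
#' cells, preserving the number of positives but destroying any
#' relationship with the similarity structure.  Used to verify that
#' cross-validation performance collapses to chance on label-shuffled
#' data.
#'
#' @param A an [AssociationMatrix].
#' @param seed RNG seed.
#' @return an [AssociationMatrix] with permuted entries.
#' @export
permuteAssociations <- function(A, seed = 42L) {
    v <- withSeed(seed, sample(A@values))
    AssociationMatrix(A@circIds, A@drugIds,
                      matrix(v, nrow(A@values), ncol(A@values)))
}
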