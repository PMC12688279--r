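# Small in-code fixtures shared across test files.

tinyDataset <- function(seed = 2L, M = 12L, N = 8L) {
    generateDataset(syntheticSpec(M = M, N = N, rank = 2L, density = 0.25,
                                  seqLen = 40L, fpLen = 32L, seed = seed))
}

tinyGraph <- function(d = tinyDataset(), knnK = 4L) {
    gC <- gipSimilarity(d$A, "circ")$sim
    gD <- gipSimilarity(d$A, "drug")$sim
    Xc <- fuseSimilarities(sequenceSimilarity(d$seqs), gC)
    Xd <- fuseSimilarities(tanimotoSimilarity(d$fps), gD)
    buildGraph(Xc, Xd, d$A, knnK)
}

tinyConfig <- function(...) {
    base <- list(encoder.hiddenDim = 8L, encoder.layers = 2L,
                 afc.dim = 8L, afc.heads = 2L, train.epochs = 5L)
    over <- list(...)
    base[names(over)] <- over
    do.call(modelConfig, base)
}
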