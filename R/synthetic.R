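#' Synthetic dataset specification
#'
#' Constructor for [SyntheticSpec].  Defaults describe a small
#' cluster-structured benchmark suitable for unit-level checks; the frozen
#' acceptance benchmark is [benchmarkSpec()].
#'
#' @param M,N numbers of circRNAs and drugs.
#' @param rank latent dimension / number of planted clusters per entity
#'   type.
#' @param density target positive rate of the association matrix.
#' @param seqLen generated sequence length.
#' @param fpLen fingerprint bit length.
#' @param noise probability that a planted association is dropped
#'   (masked to 0), emulating incomplete annotation; `0 <= noise < 0.5`.
#' @param seed RNG seed; the dataset is a pure function of the spec.
#' @return a validated [SyntheticSpec].
#' @export
syntheticSpec <- function(M = 60L, N = 40L, rank = 4L, density = 0.1,
                          seqLen = 120L, fpLen = 128L, noise = 0,
                          seed = 1L) {
    new("SyntheticSpec", M = as.integer(M), N = as.integer(N),
        rank = as.integer(rank), density = density,
        seqLen = as.integer(seqLen), fpLen = as.integer(fpLen),
        noise = noise, seed = as.integer(seed))
}

#' The frozen synthetic acceptance benchmark
#'
#' 120 circRNAs x 80 drugs with planted rank-4 cluster structure, target
#' density 0.08, 200 nt sequences, 256-bit fingerprints, 5% association
#' dropout, seed 42.  Constant across calls.
#'
#' @return a [SyntheticSpec].
#' @export
benchmarkSpec <- function() {
    syntheticSpec(M = 120L, N = 80L, rank = 4L, density = 0.08,
                  seqLen = 200L, fpLen = 256L, noise = 0.05, seed = 42L)
}

#' @rdname syntheticSpec
#' @param path YAML file path.
#' @export
readSyntheticSpec <- function(path) {
    y <- yaml::read_yaml(path)
    # YAML 1.1 reads a bare key `N` as the boolean FALSE; undo that
    names(y)[names(y) %in% c("FALSE", "F")] <- "N"
    do.call(syntheticSpec, y)
}

#' @rdname syntheticSpec
#' @param spec a [SyntheticSpec].
#' @export
writeSyntheticSpec <- function(spec, path) {
    yaml::write_yaml(
        list(M = spec@M, N = spec@N, rank = spec@rank,
             density = spec@density, seqLen = spec@seqLen,
             fpLen = spec@fpLen, noise = spec@noise, seed = spec@seed),
        path)
    invisible(path)
}

# generator constants: cluster geometry and mutation/flip rates chosen to
# give clearly separated but noisy clusters (see the methods vignette)
.SYN_CENTER_SD <- 1.2
.SYN_WITHIN_SD <- 0.4
.SYN_SEQ_MUT <- 0.10
.SYN_FP_FLIP <- 0.05
.SYN_FP_DENSITY <- 0.3

.mutateSeq <- function(template, rate) {
    bases <- c("A", "C", "G", "T")
    n <- length(template)
    hit <- stats::runif(n) < rate
    if (any(hit)) {
        repl <- vapply(template[hit],
                       function(b) sample(setdiff(bases, b), 1L),
                       character(1))
        template[hit] <- repl
    }
    paste(template, collapse = "")
}

#' Generate a synthetic circRNA-drug dataset with planted structure
#'
#' Draws latent factors for circRNAs and drugs from `rank` clusters per
#' entity type (Gaussian cluster centers, within-cluster scatter), sets
#' association probabilities through a logistic model
#' `P(A_ij = 1) = sigmoid(u_i . v_j + b)` with the bias `b` calibrated by
#' bisection so the expected density matches the spec, samples the binary
#' matrix, and then masks each planted association with probability
#' `noise`.  Host-gene sequences are generated from a cluster-specific
#' random template with per-base mutation, so within-cluster edit
#' similarity exceeds between-cluster similarity; fingerprints likewise
#' from cluster template bit vectors with bit-flip noise.  The output is
#' fully determined by `spec@seed`.
#'
#' @param spec a [SyntheticSpec].
#' @return list with `seqs` ([SequenceSet]), `fps` ([FingerprintSet]),
#'   `A` ([AssociationMatrix]) and `truth` (latent factors, cluster
#'   assignments, calibrated bias).
#' @examples
#' d <- generateDataset(syntheticSpec(M = 20, N = 10, seed = 3))
#' d$A
#' @export
generateDataset <- function(spec) {
    validObject(spec)
    withSeed(spec@seed, {
        r <- spec@rank
        circCl <- sample(rep_len(seq_len(r), spec@M))
        drugCl <- sample(rep_len(seq_len(r), spec@N))
        Cc <- matrix(stats::rnorm(r * r, sd = .SYN_CENTER_SD), r, r)
        Cd <- matrix(stats::rnorm(r * r, sd = .SYN_CENTER_SD), r, r)
        U <- Cc[circCl, , drop = FALSE] +
            matrix(stats::rnorm(spec@M * r, sd = .SYN_WITHIN_SD), spec@M)
        V <- Cd[drugCl, , drop = FALSE] +
            matrix(stats::rnorm(spec@N * r, sd = .SYN_WITHIN_SD), spec@N)
        L <- tcrossprod(U, V)
        f <- function(b) mean(stats::plogis(L + b)) - spec@density
        lo <- -50; hi <- 50
        if (f(lo) > 0 || f(hi) < 0)
            stopTyped("calibrationError",
                      "density %g not reachable by bias calibration",
                      spec@density)
        b <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
        P <- stats::plogis(L + b)
        A <- matrix(stats::rbinom(length(P), 1L, P), spec@M, spec@N)
        if (spec@noise > 0) {
            drop <- A == 1 & matrix(stats::runif(length(P)) < spec@noise,
                                    spec@M, spec@N)
            A[drop] <- 0L
        }
        circIdsV <- sprintf("circ%03d", seq_len(spec@M))
        drugIdsV <- sprintf("drug%03d", seq_len(spec@N))
        bases <- c("A", "C", "G", "T")
        seqTemplates <- lapply(seq_len(r), function(k)
            sample(bases, spec@seqLen, replace = TRUE))
        seqsChar <- vapply(seq_len(spec@M), function(i)
            .mutateSeq(seqTemplates[[circCl[i]]], .SYN_SEQ_MUT),
            character(1))
        fpTemplates <- lapply(seq_len(r), function(k)
            stats::rbinom(spec@fpLen, 1L, .SYN_FP_DENSITY))
        bits <- t(vapply(seq_len(spec@N), function(j) {
            flip <- stats::runif(spec@fpLen) < .SYN_FP_FLIP
            as.integer(xor(fpTemplates[[drugCl[j]]] == 1L, flip))
        }, integer(spec@fpLen)))
        list(seqs = SequenceSet(circIdsV, seqsChar),
             fps = FingerprintSet(drugIdsV, bits),
             A = AssociationMatrix(circIdsV, drugIdsV, A),
             truth = list(U = U, V = V, circCluster = circCl,
                          drugCluster = drugCl, bias = b))
    })
}
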