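# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a private RNG stream; caller's RNG state is untouched.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# seed derivation that stays inside 32-bit integer range
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

stopTyped <- function(class, fmt, ...) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assertScalarIn <- function(x, lo, hi, what) {
    if (length(x) != 1L || !is.finite(x) || x < lo || x > hi)
        stopTyped("rangeError", "%s must be a single value in [%g, %g]",
                  what, lo, hi)
    invisible(x)
}

blockDiag <- function(A, B) {
    out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
    out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
    out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
    out
}
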