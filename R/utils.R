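# Run code with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

# One-hot dummy matrix for class labels (n x K, colnames = levels).
dummyMatrix <- function(labels, levels = NULL) {
    f <- if (is.null(levels)) factor(labels) else factor(labels, levels)
    out <- matrix(0, length(f), nlevels(f),
                  dimnames = list(names(labels), levels(f)))
    out[cbind(seq_along(f), as.integer(f))] <- 1
    out
}

# Column standard deviations with n-1 denominator.
colSds <- function(m) {
    n <- nrow(m)
    if (n < 2L) stop("need at least 2 rows to compute standard deviations")
    mu <- colMeans(m)
    sqrt(colSums(sweep(m, 2L, mu)^2) / (n - 1L))
}
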