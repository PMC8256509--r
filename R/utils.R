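# Internal numeric helpers.

# Invert the trigamma function by Newton iteration on 1/trigamma scale.
# Used by the moment-matching estimator of the variance prior.
trigammaInverse <- function(x) {
    out <- x
    ok <- is.finite(x) & x > 0
    out[is.na(x)] <- NA_real_
    out[!is.na(x) & x > 1e7] <- 1 / sqrt(x[!is.na(x) & x > 1e7])
    out[!is.na(x) & x < 1e-6] <- 1 / x[!is.na(x) & x < 1e-6]
    mid <- ok & x <= 1e7 & x >= 1e-6
    if (any(mid)) {
        y <- 0.5 + 1 / x[mid]
        for (i in seq_len(50)) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2L)
            y <- y + dif
            if (max(-dif / y) < 1e-10) break
        }
        out[mid] <- y
    }
    out
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform unordered-pair key for edge deduplication.
edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
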