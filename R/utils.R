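# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the stream alone.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Counter-based fan-out of one user seed into independent stage seeds,
# kept inside 32-bit integer range.
deriveSeed <- function(seed, counter) {
    as.integer((as.numeric(seed) * 7919 + 104729 * counter) %% 2147483647)
}

logSumExp <- function(x) {
    x <- x[!is.infinite(x) | x > 0]  # drop -Inf terms
    if (length(x) == 0L) return(-Inf)
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable binary cross-entropy from logits.
bceFromLogits <- function(logit, target) {
    pmax(logit, 0) - logit * target + log1p(exp(-abs(logit)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
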