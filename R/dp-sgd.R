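# DP-SGD primitives for the discriminator: per-participant gradient
# clipping, Gaussian noising of the lot's gradient sum, and Poisson lot
# subsampling. Poisson sampling (each index kept independently with
# probability q) is used rather than fixed-size shuffling because the
# moments accountant's amplification bound assumes exactly that mechanism.

#' Clip a per-example gradient to a norm bound
#'
#' Returns \code{g * min(1, C / ||g||_2)}, limiting the influence any single
#' participant's gradient can exert on an update. Idempotent; gradients
#' already within the bound pass through unchanged.
#'
#' @param g numeric gradient vector.
#' @param C clip norm bound, > 0.
#' @return the clipped vector, with 2-norm <= C.
#' @examples
#' clipGradient(c(3, 4), 1)   # scaled to (0.6, 0.8)
#' @export
clipGradient <- function(g, C) {
    if (C <= 0) stop("clip norm C must be > 0")
    nrm <- sqrt(sum(g^2))
    if (nrm <= C) g else g * (C / nrm)
}

#' Average a lot's clipped gradients with Gaussian noise
#'
#' The Abadi convention: noise with sd \code{sigma * C} is added to each
#' coordinate of the \emph{sum} of clipped per-example gradients, and the
#' noised sum is divided by the (expected) lot size L:
#' \code{(1/L) (sum_i g_i + Normal(0, sigma^2 C^2 I))}. With
#' \code{sigma = 0} this is the exact mean of the clipped gradients.
#'
#' @param G matrix of clipped per-example gradients, one row per example;
#'   every row must already satisfy the norm bound (contract checked).
#' @param C clip norm the rows were clipped to.
#' @param sigma noise multiplier, >= 0.
#' @param L divisor lot size; defaults to \code{nrow(G)}. Under Poisson
#'   sampling pass the expected lot size.
#' @return the averaged noisy gradient vector. Deterministic for a fixed
#'   RNG state.
#' @export
noisyLotGradient <- function(G, C, sigma, L = nrow(G)) {
    G <- as.matrix(G)
    if (sigma < 0) stop("sigma must be >= 0")
    norms <- sqrt(rowSums(G^2))
    if (is.finite(C) && any(norms > C * (1 + 1e-8))) {
        stop("contract violation: unclipped gradient passed to noisyLotGradient")
    }
    s <- colSums(G)
    if (sigma > 0) s <- s + stats::rnorm(ncol(G), 0, sigma * C)
    s / L
}

#' Poisson-sample a lot of participant indices
#'
#' Each of the \code{n} indices is included independently with probability
#' \code{q}, so the lot size is Binomial(n, q) with mean \code{n * q} -- the
#' sampling scheme whose privacy amplification the accountant assumes.
#'
#' @param n dataset size.
#' @param q sampling rate in (0, 1].
#' @return integer vector of sampled indices (possibly empty).
#' @export
sampleLot <- function(n, q) {
    if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
    if (q == 1) return(seq_len(n))
    which(stats::runif(n) < q)
}
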