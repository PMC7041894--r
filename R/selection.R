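# Differentially private checkpoint selection. Training under DP yields a
# generator snapshot per checkpointed epoch; rather than releasing only the
# last one, several epochs are selected by utility and pooled. Because the
# utility scores consult the real training data, each selection must itself
# be private: the exponential mechanism at a small per-draw epsilon (the
# released checkpoints then cost k * epsilon on top of training).

#' Selection configuration
#'
#' @param k number of checkpoints to select (default 10).
#' @param epsilonPerSelection privacy loss per selected model (default
#'   0.05, so the default total selection budget is (0.5, 0)).
#' @param sensitivity utility sensitivity: how much one participant can
#'   move any checkpoint's utility. The default scorer averages a 0/1
#'   per-participant agreement over n real records, so its sensitivity is
#'   1/n (set when scoring).
#' @param seed integer seed for the mechanism's randomness.
#' @return a \code{SelectionConfig} list.
#' @export
selectionConfig <- function(k = 10L, epsilonPerSelection = 0.05,
                            sensitivity = NULL, seed = 1L) {
    if (k < 1L) stop("k must be >= 1")
    if (epsilonPerSelection <= 0) stop("epsilonPerSelection must be > 0")
    structure(list(k = as.integer(k),
                   epsilonPerSelection = epsilonPerSelection,
                   sensitivity = sensitivity, seed = as.integer(seed)),
              class = "SelectionConfig")
}

# Default bounded utility: nearest-centroid arm classifier fit on the
# checkpoint's synthetic records, scored by agreement with the real arms.
centroidArmScore <- function(synthetic, real, ranges) {
    Xs <- normalizeCohort(synthetic, ranges)
    Xr <- normalizeCohort(real, ranges)
    ys <- as.integer(armLabels(synthetic))
    if (length(unique(ys)) < 2L) return(0.5)
    c1 <- colMeans(Xs[ys == 1L, , drop = FALSE])
    c2 <- colMeans(Xs[ys == 2L, , drop = FALSE])
    d1 <- rowSums(sweep(Xr, 2, c1)^2)
    d2 <- rowSums(sweep(Xr, 2, c2)^2)
    pred <- ifelse(d2 < d1, 2L, 1L)
    mean(pred == as.integer(armLabels(real)))
}

#' Score generator checkpoints by downstream utility
#'
#' For each checkpoint, generates a synthetic cohort, trains a lightweight
#' arm classifier on it (nearest centroid by default) and scores agreement
#' with the real training cohort's arms -- a bounded utility in [0, 1], as
#' the exponential mechanism's sensitivity control requires. The scorer is
#' the only point at which selection touches real data.
#'
#' @param checkpoints list of \linkS4class{Checkpoint}s.
#' @param real the real training \linkS4class{Cohort}.
#' @param nSynthetic synthetic sample size per checkpoint.
#' @param scorer function(syntheticCohort, realCohort, ranges) -> utility in
#'   [0, 1].
#' @param ranges normalisation ranges.
#' @param seed integer seed (generation is deterministic per checkpoint).
#' @return the checkpoints with \code{utility} slots filled.
#' @export
scoreCheckpoints <- function(checkpoints, real, nSynthetic = 1000L,
                             scorer = centroidArmScore,
                             ranges = defaultRanges(cohortVariables(real)),
                             seed = 1L) {
    lapply(seq_along(checkpoints), function(i) {
        ck <- checkpoints[[i]]
        syn <- generateCohort(ck@generator, nSynthetic,
                              seed = deriveSeed(seed, i))
        u <- scorer(syn, real, ranges)
        if (is.na(u) || u < 0 || u > 1) {
            stop("scorer returned an unbounded utility; must lie in [0, 1]")
        }
        ck@utility <- u
        ck
    })
}

#' Select checkpoints with the exponential mechanism
#'
#' Draws \code{k} checkpoints without replacement, each draw picking index
#' i with probability proportional to \code{exp(epsilon * u_i / (2 *
#' sensitivity))}. Each draw is (epsilonPerSelection, 0)-differentially
#' private, so the total selection budget is
#' \code{(k * epsilonPerSelection, 0)} by basic composition.
#'
#' @param utilities numeric utilities in [0, 1], one per checkpoint.
#' @param config a [selectionConfig()]; its \code{sensitivity} must be set
#'   (use 1/n for the default agreement scorer over n real records).
#' @return list with \code{selected} (indices in draw order) and
#'   \code{budget} (a \linkS4class{PrivacyBudget}).
#' @export
selectModels <- function(utilities, config = selectionConfig(sensitivity = 1)) {
    k <- config$k
    if (k > length(utilities)) stop("k exceeds the number of checkpoints")
    if (any(utilities < 0 | utilities > 1)) {
        stop("utilities must be bounded in [0, 1]")
    }
    if (is.null(config$sensitivity) || config$sensitivity <= 0) {
        stop("config$sensitivity must be a positive utility sensitivity")
    }
    eps <- config$epsilonPerSelection
    withSeed(config$seed, {
        remaining <- seq_along(utilities)
        chosen <- integer(0)
        for (d in seq_len(k)) {
            w <- eps * utilities[remaining] / (2 * config$sensitivity)
            p <- exp(w - max(w))
            pick <- sample(length(remaining), 1L, prob = p)
            chosen <- c(chosen, remaining[pick])
            remaining <- remaining[-pick]
        }
        list(selected = chosen, budget = privacyBudget(k * eps, 0))
    })
}

#' Pool synthetic generation across selected checkpoints
#'
#' Splits \code{nTotal} as evenly as possible across the selected
#' checkpoints (remainder to the earliest), generates from each and
#' concatenates. Pure post-processing: no ledger access.
#'
#' @param checkpoints list of selected \linkS4class{Checkpoint}s (or
#'   generator models).
#' @param nTotal total synthetic participants.
#' @param armMix passed to [generateCohort()].
#' @param seed integer seed.
#' @return the pooled \linkS4class{Cohort}.
#' @export
poolGenerate <- function(checkpoints, nTotal, armMix = 0.5, seed = 1L) {
    k <- length(checkpoints)
    stopifnot(k >= 1L)
    sizes <- rep(nTotal %/% k, k) + c(rep(1L, nTotal %% k),
                                      rep(0L, k - nTotal %% k))
    parts <- lapply(seq_len(k), function(i) {
        generateCohort(checkpoints[[i]], sizes[i], armMix = armMix,
                       seed = deriveSeed(seed, i))
    })
    bindCohorts(parts)
}
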