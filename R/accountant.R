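# Moments accountant for the subsampled Gaussian mechanism.
#
# One DP-SGD step releases the clipped, noised gradient sum of a Poisson
# lot sampled at rate q, noised with sd sigma * C. Its privacy-loss moment
# generating function is bounded, for integer order lambda, by
#
#   alpha(lambda) = log E_{z ~ nu} [ (nu(z) / mu0(z))^lambda ]
#
# with mu0 = N(0, sigma^2), mu1 = N(1, sigma^2), nu = (1-q) mu0 + q mu1.
# The binomial expansion of the integrand gives the exact closed form
#
#   alpha(lambda) = logsumexp_{k=0..lambda+1} [ C(lambda+1, k)
#                     + (lambda+1-k) log(1-q) + k log(q)
#                     + k (k-1) / (2 sigma^2) ]
#
# which reduces to lambda (lambda + 1) / (2 sigma^2) at q = 1 (the plain
# Gaussian mechanism). Log moments add over steps, and
# delta = min_lambda exp(alpha(lambda) - lambda * epsilon).

# Per-step log moment alpha_step(lambda) for one subsampled Gaussian step.
stepLogMoment <- function(q, sigma, lambdas) {
    if (q == 0) return(rep(0, length(lambdas)))
    if (sigma <= 0) stop("sigma = 0 with q > 0 gives infinite log moments")
    vapply(lambdas, function(lam) {
        k <- 0:(lam + 1L)
        terms <- lchoose(lam + 1L, k) + k * log(q) + k * (k - 1) / (2 * sigma^2)
        if (q < 1) {
            terms <- terms + (lam + 1L - k) * log1p(-q)
        } else {
            terms[k < lam + 1L] <- -Inf  # only the k = lambda + 1 term survives
        }
        logSumExp(terms)
    }, numeric(1))
}

#' Create a moments-accountant ledger
#'
#' @param q Poisson sampling rate of each lot (expected lot size / n).
#' @param sigma noise multiplier of the Gaussian mechanism.
#' @param lambdas integer moment orders to track (default 1..32).
#' @return a \linkS4class{MomentsLedger} with zero steps taken.
#' @examples
#' led <- momentsLedger(q = 0.01, sigma = 2)
#' led <- accumulateSteps(led, 1000 * 100)  # 1000 epochs of 100 lots
#' epsilonAtDelta(led, 1e-5)
#' @export
momentsLedger <- function(q, sigma, lambdas = 1:32) {
    lambdas <- as.integer(lambdas)
    new("MomentsLedger", q = q, sigma = sigma, steps = 0,
        lambdas = lambdas,
        stepLogMoments = stepLogMoment(q, sigma, lambdas),
        logMoments = rep(0, length(lambdas)))
}

#' Advance a ledger by noisy gradient steps
#'
#' Log moments are additive under composition, so \code{steps} steps add
#' \code{steps * alpha_step(lambda)}; accumulating in chunks is exactly
#' equivalent to accumulating once.
#'
#' @param ledger a \linkS4class{MomentsLedger}.
#' @param steps number of mechanism invocations to add (>= 0).
#' @return the advanced ledger.
#' @export
accumulateSteps <- function(ledger, steps) {
    if (steps < 0) stop("steps must be >= 0")
    ledger@steps <- ledger@steps + steps
    ledger@logMoments <- ledger@logMoments + steps * ledger@stepLogMoments
    validObject(ledger)
    ledger
}

#' delta achieved at a given epsilon
#'
#' The tail bound \code{delta = min_lambda exp(alpha(lambda) - lambda *
#' epsilon)}, clamped to [0, 1]. A ledger with zero steps has touched no
#' data and reports delta = 0.
#'
#' @param ledger a \linkS4class{MomentsLedger}.
#' @param epsilon privacy loss, >= 0.
#' @return delta in [0, 1], non-increasing in epsilon.
#' @export
deltaAtEpsilon <- function(ledger, epsilon) {
    if (epsilon < 0) stop("epsilon must be >= 0")
    if (ledger@steps == 0) return(0)
    min(1, exp(min(ledger@logMoments - ledger@lambdas * epsilon)))
}

#' Smallest epsilon achieving a given delta
#'
#' Inverts [deltaAtEpsilon()] by bisection to 1e-4 tolerance.
#'
#' @param ledger a \linkS4class{MomentsLedger}.
#' @param delta target failure probability in (0, 1).
#' @return the smallest epsilon with \code{deltaAtEpsilon(ledger, epsilon)
#'   <= delta}.
#' @export
epsilonAtDelta <- function(ledger, delta) {
    if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
    if (deltaAtEpsilon(ledger, 0) <= delta) return(0)
    hi <- 1
    while (deltaAtEpsilon(ledger, hi) > delta) {
        hi <- hi * 2
        if (hi > 1e9) {
            stop("delta is unreachable under the accumulated moment bound")
        }
    }
    lo <- hi / 2
    while (hi - lo > 1e-4) {
        mid <- (lo + hi) / 2
        if (deltaAtEpsilon(ledger, mid) <= delta) hi <- mid else lo <- mid
    }
    hi
}

#' Privacy-spend curve across training epochs
#'
#' Tabulates delta as a function of epoch for several epsilon values, the
#' view used to pick how long a private run may train within a budget
#' (e.g. reading off that a given (q, sigma) allows 1000 epochs at
#' epsilon = 3.5 with delta below 1e-5).
#'
#' @param q,sigma mechanism parameters.
#' @param lotsPerEpoch noisy steps per epoch (ceiling(n / L)).
#' @param epochs epochs at which to evaluate.
#' @param epsilons epsilon values to tabulate.
#' @return data.frame (epoch, epsilon, delta).
#' @export
privacyCurve <- function(q, sigma, lotsPerEpoch,
                         epochs = seq(50, 1000, by = 50),
                         epsilons = c(0.5, 1, 2, 3.5)) {
    base <- momentsLedger(q, sigma)
    out <- expand.grid(epoch = epochs, epsilon = epsilons)
    out$delta <- mapply(function(e, eps) {
        deltaAtEpsilon(accumulateSteps(base, e * lotsPerEpoch), eps)
    }, out$epoch, out$epsilon)
    out
}

#' Compose privacy budgets
#'
#' Basic composition: epsilons and deltas add component-wise. Composing the
#' training budget at delta = 1e-5 with ten (0.05, 0) model selections, for
#' example, turns a training epsilon of 3.5 into a total budget of
#' (4, 1e-5).
#'
#' @param budgets list of \linkS4class{PrivacyBudget} objects.
#' @return the composed \linkS4class{PrivacyBudget}.
#' @export
composeBudgets <- function(budgets) {
    if (length(budgets) == 0L) stop("need at least one budget")
    privacyBudget(sum(vapply(budgets, function(b) b@epsilon, numeric(1))),
                  sum(vapply(budgets, function(b) b@delta, numeric(1))))
}

setMethod("show", "PrivacyBudget", function(object) {
    cat(sprintf("PrivacyBudget (epsilon = %g, delta = %g)\n",
                object@epsilon, object@delta))
})

setMethod("show", "MomentsLedger", function(object) {
    cat(sprintf("MomentsLedger: q = %g, sigma = %g, steps = %g\n",
                object@q, object@sigma, object@steps))
    if (object@steps > 0) {
        cat(sprintf("  epsilon at delta = 1e-5: %.4f\n",
                    epsilonAtDelta(object, 1e-5)))
    }
})

#' Bound an adversary's updated probability estimate
#'
#' Differential privacy at loss epsilon bounds how much an observer's
#' estimate of any per-individual event probability can grow because the
#' individual joined the study. The default follows the small-epsilon
#' linearised convention \code{prior * (1 + epsilon)} (so a 0.09% prior
#' under epsilon = 1 is bounded by 0.18%); \code{convention = "exp"} gives
#' the exact \code{prior * exp(epsilon)} factor. Both are capped at 1.
#'
#' @param prior prior probability in [0, 1].
#' @param epsilon privacy loss, >= 0.
#' @param convention \code{"linear"} (default) or \code{"exp"}.
#' @return the bounded posterior probability.
#' @export
dpProbabilityBound <- function(prior, epsilon, convention = c("linear", "exp")) {
    convention <- match.arg(convention)
    if (prior < 0 || prior > 1) stop("prior must lie in [0, 1]")
    if (epsilon < 0) stop("epsilon must be >= 0")
    factor <- if (convention == "linear") 1 + epsilon else exp(epsilon)
    min(1, prior * factor)
}

#' Premium implied by a bounded event probability
#'
#' Adds the expected cost of a bounded adverse event to a base premium:
#' \code{base + cost * probability}. With a $3000 base, a $30,000 event and
#' the 0.18% DP bound this is $3054; with a tripled 0.09% risk it is $3027.
#'
#' @param basePremium base premium (currency units).
#' @param eventCost cost if the event occurs.
#' @param eventProbability (bounded) event probability.
#' @return the bounded premium.
#' @export
premiumBound <- function(basePremium, eventCost, eventProbability) {
    if (basePremium < 0 || eventCost < 0 || eventProbability < 0) {
        stop("inputs must be non-negative")
    }
    basePremium + eventCost * eventProbability
}
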