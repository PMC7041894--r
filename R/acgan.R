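# Auxiliary-classifier GAN over participant matrices. The generator maps
# (noise z, requested treatment arm) to a normalised participant record;
# the discriminator scores records as real vs generated and additionally
# predicts the arm -- the auxiliary task that makes the generator produce
# arm-consistent participants. Only the discriminator ever touches real
# data, so it alone is trained under DP-SGD in private mode; the generator
# learns purely from discriminator feedback and generation is free
# post-processing.

armToIndex <- function(arm, levels) {
    if (is.factor(arm)) arm <- as.character(arm)
    if (is.numeric(arm)) {
        idx <- as.integer(arm)
        if (!all(idx %in% c(1L, 2L))) stop("numeric arm must be 1 or 2")
        return(idx)
    }
    idx <- match(arm, levels)
    if (anyNA(idx)) stop("arm label not among model arm levels")
    idx
}

#' Generator forward pass
#'
#' @param model a generator \linkS4class{GanModel}.
#' @param z matrix of latent draws, one row per sample (standard normal).
#' @param arm one arm label per row of \code{z} (factor, character, or
#'   level index 1/2).
#' @return matrix of normalised participant records in [-1, 1], one row per
#'   sample. Deterministic given (z, arm, model).
#' @export
generatorForward <- function(model, z, arm) {
    stopifnot(model@role == "generator")
    z <- as.matrix(z)
    if (ncol(z) != model@arch$latentDim) {
        stop(sprintf("z has %d columns; latentDim is %d",
                     ncol(z), model@arch$latentDim))
    }
    idx <- armToIndex(arm, model@arch$armLevels)
    if (length(idx) != nrow(z)) stop("need one arm label per z row")
    genForwardInternal(model, z, idx)$Y
}

#' Discriminator forward pass
#'
#' @param model a discriminator \linkS4class{GanModel}.
#' @param x matrix of normalised records in [-1, 1], one row per sample.
#' @return data.frame with \code{source} (real-vs-fake score, the head's
#'   logit; larger means more real) and \code{armProb} (probability of the
#'   second arm level, in [0, 1]).
#' @export
discriminatorForward <- function(model, x) {
    stopifnot(model@role == "discriminator")
    x <- as.matrix(x)
    if (ncol(x) != model@arch$inDim) {
        stop(sprintf("x has %d columns; discriminator expects %d",
                     ncol(x), model@arch$inDim))
    }
    fw <- discForwardInternal(model, x)
    data.frame(source = fw$srcLogit, armProb = sigmoid(fw$armLogit))
}

#' AC-GAN losses for a real/fake batch pair
#'
#' The discriminator loss is binary cross-entropy on the source head (real
#' records labelled 1, generated ones 0) plus arm-classification
#' cross-entropy on both batches; the generator loss is the adversarial
#' source term (fakes labelled real) plus the same arm term on fakes, so
#' the generator is rewarded for class-consistent output.
#'
#' @param disc a discriminator \linkS4class{GanModel}.
#' @param xReal,xFake normalised batches (rows = samples).
#' @param armReal,armFake arm labels for each batch.
#' @return list with per-sample-averaged \code{dLoss} and \code{gLoss}.
#' @export
acganLosses <- function(disc, xReal, xFake, armReal, armFake) {
    if (nrow(as.matrix(xReal)) == 0L || nrow(as.matrix(xFake)) == 0L) {
        stop("batches must be non-empty")
    }
    yR <- armToIndex(armReal, disc@arch$armLevels) - 1
    yF <- armToIndex(armFake, disc@arch$armLevels) - 1
    fr <- discForwardInternal(disc, xReal)
    ff <- discForwardInternal(disc, xFake)
    dLoss <- mean(bceFromLogits(fr$srcLogit, 1) +
                  bceFromLogits(fr$armLogit, yR)) +
             mean(bceFromLogits(ff$srcLogit, 0) +
                  bceFromLogits(ff$armLogit, yF))
    gLoss <- mean(bceFromLogits(ff$srcLogit, 1) +
                  bceFromLogits(ff$armLogit, yF))
    list(dLoss = dLoss, gLoss = gLoss)
}

# Discriminator loss gradient for one update. In private mode,
# per-participant gradients from the real lot are clipped to C, their sum
# is noised with sd sigma * C and divided by the expected lot size L; the
# fake-batch term is an ordinary mean gradient (it involves no real data).
# The optimizer consuming the returned gradient sees only the privatised
# quantity, so any update rule applied to it is post-processing.
discriminatorGradient <- function(disc, Xr, yR, Xf, yF,
                                  private = FALSE, C = Inf, sigma = 0,
                                  L = nrow(Xr)) {
    grads <- NULL
    if (nrow(Xr) > 0L) {
        fw <- discForwardInternal(disc, Xr)
        bk <- discBackwardInternal(disc, fw,
                                   dSrc = sigmoid(fw$srcLogit) - 1,
                                   dArm = sigmoid(fw$armLogit) - yR)
        if (private) {
            nrm <- sqrt(discPerExampleNormSq(fw, bk))
            cl <- pmin(1, C / pmax(nrm, 1e-12))
            grads <- discGradients(fw, bk, cl)
        } else {
            grads <- discGradients(fw, bk, rep(1 / nrow(Xr), nrow(Xr)))
        }
    }
    if (private) {
        if (is.null(grads)) {  # empty Poisson lot: the mechanism still fires
            zero <- lapply(disc@params, function(x) x * 0)
            grads <- zero[c("W1", "b1", "W2", "b2", "ws", "bs", "wa", "ba")]
        }
        if (sigma > 0) {
            grads <- lapply(grads, function(g) {
                g + stats::rnorm(length(g), 0, sigma * C)
            })
        }
        grads <- lapply(grads, function(g) g / L)
    }
    ffw <- discForwardInternal(disc, Xf)
    fbk <- discBackwardInternal(disc, ffw,
                                dSrc = sigmoid(ffw$srcLogit),
                                dArm = sigmoid(ffw$armLogit) - yF)
    fgrads <- discGradients(ffw, fbk, rep(1 / nrow(Xf), nrow(Xf)))
    Map(`+`, grads, fgrads)
}

# One generator (Adam) update against the current discriminator.
generatorStep <- function(gen, disc, z, armIdx, lr, state) {
    gfw <- genForwardInternal(gen, z, armIdx)
    dfw <- discForwardInternal(disc, gfw$Y)
    y <- armIdx - 1
    B <- nrow(z)
    bk <- discBackwardInternal(disc, dfw,
                               dSrc = (sigmoid(dfw$srcLogit) - 1) / B,
                               dArm = (sigmoid(dfw$armLogit) - y) / B)
    grads <- genGradients(gen, gfw, bk$deltaX, armIdx)
    adamStep(gen, grads, state, lr)
}

# Ledger stand-in for nonprivate runs: every step on real data is recorded,
# but the log moments are infinite -- no (epsilon, delta) guarantee exists.
nonprivateLedger <- function(q, lambdas = 1:32) {
    led <- new("MomentsLedger", q = q, sigma = 0, steps = 0,
               lambdas = as.integer(lambdas),
               stepLogMoments = rep(Inf, length(lambdas)),
               logMoments = rep(0, length(lambdas)))
    led
}

#' Train an AC-GAN on a cohort
#'
#' Runs adversarial training on the normalised participant matrix. In
#' private mode the discriminator -- the only network that accesses real
#' data -- is updated by DP-SGD: Poisson lots at rate q = L/n,
#' per-participant gradient clipping at \code{clipNorm}, Gaussian noise at
#' \code{noiseMultiplier * clipNorm}, with every noisy step recorded in a
#' \linkS4class{MomentsLedger}. Generator updates never touch the ledger.
#' In nonprivate mode the ledger still counts real-data steps but carries
#' infinite log moments (no guarantee).
#'
#' Runs are reproducible for a fixed seed and fixed BLAS/thread settings;
#' differing hardware may change floating-point summation order.
#'
#' @param cohort a complete \linkS4class{Cohort}; normalised internally via
#'   [normalizeCohort()].
#' @param config a [trainConfig()].
#' @param ranges per-variable normalisation ranges.
#' @param verbose print per-epoch losses every 50 epochs.
#' @return list with \code{checkpoints} (one per \code{checkpointEvery}
#'   epochs, plus the final epoch), \code{generator}, \code{discriminator},
#'   \code{discSnapshots} (discriminator state at each checkpoint epoch,
#'   for diagnostics such as tracking held-out accuracy), \code{ledger},
#'   \code{history} (per-epoch mean losses) and \code{config}.
#' @export
trainAcgan <- function(cohort, config = trainConfig(),
                       ranges = defaultRanges(cohortVariables(cohort)),
                       verbose = FALSE) {
    validObject(config)
    n <- nParticipants(cohort)
    L <- config@lotSize
    if (L > n) stop("lotSize exceeds the cohort size")
    X <- normalizeCohort(cohort, ranges)
    levels <- levels(armLabels(cohort))
    armIdx <- as.integer(armLabels(cohort))
    q <- L / n
    outDim <- ncol(X)
    ledger <- if (config@private) {
        momentsLedger(q, config@noiseMultiplier)
    } else {
        nonprivateLedger(q)
    }
    stepsPerEpoch <- ceiling(n / L)
    checkpoints <- list()
    discSnapshots <- list()
    history <- data.frame(epoch = integer(), dLoss = numeric(),
                          gLoss = numeric())
    withSeed(config@seed, {
        gen <- initGenerator(config@latentDim, config@embedDim,
                             config@hidden, outDim, armLevels = levels,
                             visits = visitSchedule(cohort),
                             variables = cohortVariables(cohort),
                             ranges = ranges)
        disc <- initDiscriminator(outDim, config@hidden, armLevels = levels)
        adam <- initAdam(gen@params)
        adamD <- initAdam(disc@params)
        for (epoch in seq_len(config@epochs)) {
            dSum <- 0; gSum <- 0
            if (config@private) {
                for (s in seq_len(stepsPerEpoch)) {
                    idx <- sampleLot(n, q)
                    zf <- matrix(stats::rnorm(L * config@latentDim), L)
                    af <- sample(1:2, L, replace = TRUE)
                    Xf <- genForwardInternal(gen, zf, af)$Y
                    if (length(idx) > 0L) {
                        loss <- acganLosses(disc, X[idx, , drop = FALSE],
                                            Xf, armIdx[idx], af)
                        dSum <- dSum + loss$dLoss
                        gSum <- gSum + loss$gLoss
                    }
                    dg <- discriminatorGradient(
                        disc, X[idx, , drop = FALSE], armIdx[idx] - 1,
                        Xf, af - 1, private = TRUE,
                        C = config@clipNorm, sigma = config@noiseMultiplier,
                        L = L)
                    upD <- adamStep(disc, dg, adamD, config@learningRate)
                    disc <- upD$model; adamD <- upD$state
                    zg <- matrix(stats::rnorm(L * config@latentDim), L)
                    ag <- sample(1:2, L, replace = TRUE)
                    up <- generatorStep(gen, disc, zg, ag,
                                        config@gLearningRate, adam)
                    gen <- up$model; adam <- up$state
                }
                ledger <- accumulateSteps(ledger, stepsPerEpoch)
            } else {
                perm <- sample.int(n)
                starts <- seq(1, n, by = L)
                for (s0 in starts) {
                    idx <- perm[s0:min(s0 + L - 1L, n)]
                    B <- length(idx)
                    zf <- matrix(stats::rnorm(B * config@latentDim), B)
                    af <- sample(1:2, B, replace = TRUE)
                    Xf <- genForwardInternal(gen, zf, af)$Y
                    loss <- acganLosses(disc, X[idx, , drop = FALSE], Xf,
                                        armIdx[idx], af)
                    dSum <- dSum + loss$dLoss
                    gSum <- gSum + loss$gLoss
                    dg <- discriminatorGradient(
                        disc, X[idx, , drop = FALSE], armIdx[idx] - 1,
                        Xf, af - 1, private = FALSE)
                    upD <- adamStep(disc, dg, adamD, config@learningRate)
                    disc <- upD$model; adamD <- upD$state
                    zg <- matrix(stats::rnorm(B * config@latentDim), B)
                    ag <- sample(1:2, B, replace = TRUE)
                    up <- generatorStep(gen, disc, zg, ag,
                                        config@gLearningRate, adam)
                    gen <- up$model; adam <- up$state
                }
                ledger <- accumulateSteps(ledger, length(starts))
            }
            history[nrow(history) + 1L, ] <-
                list(epoch, dSum / stepsPerEpoch, gSum / stepsPerEpoch)
            if (verbose && epoch %% 50 == 0) {
                message(sprintf("epoch %d: d_loss %.3f", epoch,
                                dSum / stepsPerEpoch))
            }
            if (epoch %% config@checkpointEvery == 0L ||
                epoch == config@epochs) {
                checkpoints[[length(checkpoints) + 1L]] <-
                    new("Checkpoint", epoch = epoch, generator = gen,
                        ledger = ledger, utility = NA_real_)
                discSnapshots[[length(discSnapshots) + 1L]] <- disc
            }
        }
    })
    list(checkpoints = checkpoints, generator = if (config@epochs > 0) gen,
         discriminator = if (config@epochs > 0) disc,
         discSnapshots = discSnapshots,
         ledger = ledger, history = history, config = config)
}

#' Generate a synthetic cohort from a trained generator
#'
#' Draws latent noise, requests arms in deterministic proportions, and maps
#' the generator output back to measurement units (values clamped to their
#' ranges, medication counts rounded to non-negative integers). Generation
#' is post-processing of the trained model: it never reads or advances the
#' privacy ledger.
#'
#' @param generator a generator \linkS4class{GanModel} (or
#'   \linkS4class{Checkpoint}).
#' @param n number of participants to generate, > 0.
#' @param armMix proportion assigned to the second arm level (e.g.
#'   intensive); counts are exact (\code{round(n * armMix)}), not sampled.
#' @param seed integer seed; same seed, same cohort.
#' @return a denormalised \linkS4class{Cohort}.
#' @export
generateCohort <- function(generator, n, armMix = 0.5, seed = 1L) {
    if (is(generator, "Checkpoint")) generator <- generator@generator
    stopifnot(is(generator, "GanModel"), generator@role == "generator")
    if (n <= 0) stop("n must be > 0")
    arch <- generator@arch
    n2 <- round(n * armMix)
    idx <- c(rep(1L, n - n2), rep(2L, n2))
    withSeed(seed, {
        z <- matrix(stats::rnorm(n * arch$latentDim), n)
        Y <- genForwardInternal(generator, z, idx)$Y
        denormalizeMatrix(Y, arm = arch$armLevels[idx],
                          visits = arch$visits, variables = arch$variables,
                          ranges = arch$ranges,
                          countVariables = arch$countVariables,
                          ids = sprintf("S%06d", seq_len(n)),
                          levels = arch$armLevels)
    })
}

#' Held-out discriminator accuracy
#'
#' Source-classification accuracy of a discriminator on held-out real
#' records versus an equal number of freshly generated ones (threshold 0.5
#' on the source probability). Near 50% indicates the generator has reached
#' the point where real and synthetic records cannot be told apart.
#'
#' @param disc discriminator \linkS4class{GanModel}.
#' @param gen generator \linkS4class{GanModel}.
#' @param cohort held-out real \linkS4class{Cohort}.
#' @param ranges normalisation ranges (must match training).
#' @param seed seed for the generated batch.
#' @return accuracy in [0, 1].
#' @export
discriminatorAccuracy <- function(disc, gen, cohort,
                                  ranges = defaultRanges(cohortVariables(cohort)),
                                  seed = 1L) {
    Xr <- normalizeCohort(cohort, ranges)
    n <- nrow(Xr)
    syn <- generateCohort(gen, n, armMix = 0.5, seed = seed)
    Xf <- normalizeCohort(syn, ranges)
    pr <- sigmoid(discriminatorForward(disc, Xr)$source)
    pf <- sigmoid(discriminatorForward(disc, Xf)$source)
    (sum(pr > 0.5) + sum(pf <= 0.5)) / (2 * n)
}

setMethod("show", "GanModel", function(object) {
    np <- sum(vapply(object@params, length, numeric(1)))
    cat(sprintf("GanModel <%s> with %d parameters\n", object@role, np))
})

setMethod("show", "Checkpoint", function(object) {
    cat(sprintf("Checkpoint at epoch %d (utility: %s)\n", object@epoch,
                ifelse(is.na(object@utility), "unscored",
                       sprintf("%.3f", object@utility))))
})
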