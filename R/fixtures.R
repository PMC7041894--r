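# Synthetic-fixture generators: a two-arm BP-trial simulator and a
# critical-care vitals simulator. These stand in for access-restricted
# trial/EHR data so the whole pipeline is runnable and testable; their
# defaults are declared fixture constants, not estimates of any real study.

#' Parameters of the two-arm blood-pressure trial simulator
#'
#' The simulator emulates the structure of an intensive-vs-standard
#' BP-lowering trial: arm-specific SBP control targets, medication
#' titration when a participant is above their arm's goal, mean-reverting
#' SBP dynamics giving time-decaying cross-visit correlation, and DBP
#' linearly coupled to SBP.
#'
#' Titration uses the protocol goals (120 mmHg intensive / 140 mmHg
#' standard) while mean reversion pulls towards \code{armTargets} (how
#' tightly the simulated physician actually controls each arm, default
#' 120/135); keeping these distinct yields above-goal titration events at a
#' controllable rate.
#'
#' @param nParticipants cohort size.
#' @param pIntensive probability of randomisation to the intensive arm.
#' @param baselineSbpMean,baselineSbpSd baseline SBP distribution (mmHg);
#'   draws truncated to [90, 200].
#' @param armTargets named mmHg targets the SBP trajectory reverts to.
#' @param goals named mmHg protocol goals triggering titration.
#' @param kappa per-visit mean-reversion rate in (0, 1].
#' @param noiseSd per-visit SBP innovation sd (mmHg).
#' @param pAddMed probability a medication is added at a transition whose
#'   starting SBP is above the arm's goal.
#' @param dbpSlope,dbpIntercept,dbpNoiseSd DBP = slope * SBP + intercept +
#'   Normal(0, sd) (mmHg).
#' @param med0Mean Poisson mean of the baseline medication count, truncated
#'   to [0, 6].
#' @param visits visit schedule.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return a \code{TrialSimParams} list.
#' @export
trialSimParams <- function(nParticipants = 6000L, pIntensive = 0.5,
                           baselineSbpMean = 140, baselineSbpSd = 15,
                           armTargets = c(standard = 135, intensive = 120),
                           goals = c(standard = 140, intensive = 120),
                           kappa = 0.4, noiseSd = 8, pAddMed = 0.3,
                           dbpSlope = 0.5, dbpIntercept = 8, dbpNoiseSd = 6,
                           med0Mean = 2, visits = cohortSchema()$visits,
                           seed = 1L) {
    p <- list(nParticipants = as.integer(nParticipants),
              pIntensive = pIntensive, baselineSbpMean = baselineSbpMean,
              baselineSbpSd = baselineSbpSd, armTargets = armTargets,
              goals = goals, kappa = kappa, noiseSd = noiseSd,
              pAddMed = pAddMed, dbpSlope = dbpSlope,
              dbpIntercept = dbpIntercept, dbpNoiseSd = dbpNoiseSd,
              med0Mean = med0Mean, visits = visits, seed = as.integer(seed))
    class(p) <- "TrialSimParams"
    validateTrialSimParams(p)
    p
}

validateTrialSimParams <- function(p) {
    probs <- c(pIntensive = p$pIntensive, pAddMed = p$pAddMed)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (p$kappa < 0 || p$kappa > 1) stop("kappa must lie in [0, 1]")
    if (p$noiseSd < 0 || p$dbpNoiseSd < 0 || p$baselineSbpSd <= 0) {
        stop("standard deviations must be positive")
    }
    if (p$nParticipants < 1L) stop("nParticipants must be >= 1")
    if (!all(c("standard", "intensive") %in% names(p$armTargets)) ||
        !all(c("standard", "intensive") %in% names(p$goals))) {
        stop("armTargets and goals must name both arms")
    }
    invisible(p)
}

#' Simulate a two-arm blood-pressure trial cohort
#'
#' Per participant: arm ~ Bernoulli(pIntensive); SBP_0 ~ Normal(baseline)
#' truncated to [90, 200] mmHg; meds_0 ~ Poisson(med0Mean) truncated to
#' [0, 6]. At each visit transition, a medication is added with probability
#' \code{pAddMed} when the current SBP exceeds the arm's goal (counts capped
#' at 10), and SBP evolves by mean reversion towards the arm target,
#' \code{SBP' = SBP + kappa * (target - SBP) + Normal(0, noiseSd)}. DBP is
#' \code{dbpSlope * SBP + dbpIntercept + Normal(0, dbpNoiseSd)} at every
#' visit. The mean-reverting dynamics give cross-visit SBP correlations
#' that decay with lag.
#'
#' @param params a [trialSimParams()] list.
#' @return a complete \linkS4class{Cohort} (variables SBP, DBP, MEDS),
#'   deterministic for a fixed seed.
#' @examples
#' co <- simulateTrial(trialSimParams(nParticipants = 100, seed = 7))
#' table(armLabels(co))
#' @export
simulateTrial <- function(params = trialSimParams()) {
    validateTrialSimParams(params)
    p <- params
    nv <- length(p$visits)
    withSeed(p$seed, {
        n <- p$nParticipants
        arm <- ifelse(stats::runif(n) < p$pIntensive, "intensive", "standard")
        target <- p$armTargets[arm]
        goal <- p$goals[arm]
        sbp <- matrix(NA_real_, n, nv)
        meds <- matrix(NA_real_, n, nv)
        sbp0 <- stats::rnorm(n, p$baselineSbpMean, p$baselineSbpSd)
        sbp[, 1] <- pmin(pmax(sbp0, 90), 200)
        meds[, 1] <- pmin(stats::rpois(n, p$med0Mean), 6)
        for (t in seq_len(nv - 1L)) {
            above <- sbp[, t] > goal
            add <- above & (stats::runif(n) < p$pAddMed)
            meds[, t + 1L] <- pmin(meds[, t] + add, 10)
            sbp[, t + 1L] <- sbp[, t] + p$kappa * (target - sbp[, t]) +
                stats::rnorm(n, 0, p$noiseSd)
        }
        dbp <- p$dbpSlope * sbp + p$dbpIntercept +
            matrix(stats::rnorm(n * nv, 0, p$dbpNoiseSd), n, nv)
        Cohort(cbind(sbp, dbp, meds), arm = arm, visits = p$visits,
               variables = c("SBP", "DBP", "MEDS"),
               levels = c("standard", "intensive"))
    })
}

#' Simulate a critical-care vitals table with a heart-failure label
#'
#' Emulates the EHR prediction task's input: a long-format event table of
#' nine vital signs with at least five timestamped measurements for most
#' patients, a diagnosis list assigning heart-failure ICD-9 codes to cases,
#' and the generating case indicator. Case patients' vitals are shifted by
#' \code{effectSize} standard deviations, so \code{effectSize = 0} carries
#' no signal (downstream classifiers should sit at AUROC 0.5).
#'
#' @param nPatients number of patients.
#' @param pCase case probability.
#' @param effectSize case mean shift, in units of each vital's sd.
#' @param fracComplete fraction of patients given >= 5 measurements of every
#'   vital; the rest receive only 4 of one vital and are dropped by the
#'   complete-case rule.
#' @param seed integer seed.
#' @return list with \code{events} (patient_id, variable, time, value),
#'   \code{diagnoses} (patient_id, code) and \code{labels} (named 0/1).
#' @export
simulateEhr <- function(nPatients, pCase = 2110 / 8260, effectSize = 0.6,
                        fracComplete = 0.95, seed = 1L) {
    if (pCase < 0 || pCase > 1) stop("pCase must lie in [0, 1]")
    if (fracComplete < 0 || fracComplete > 1) {
        stop("fracComplete must lie in [0, 1]")
    }
    vars <- vitalsVariables()
    mu <- c(map = 80, art_sbp = 120, art_dbp = 65, bpm = 85, resp_rate = 18,
            spo2 = 97, ni_map = 80, ni_sbp = 118, ni_dbp = 64)
    sd <- c(map = 10, art_sbp = 15, art_dbp = 10, bpm = 15, resp_rate = 4,
            spo2 = 2, ni_map = 10, ni_sbp = 15, ni_dbp = 10)
    withSeed(seed, {
        ids <- sprintf("M%05d", seq_len(nPatients))
        case <- as.integer(stats::runif(nPatients) < pCase)
        complete <- stats::runif(nPatients) < fracComplete
        shortVar <- sample.int(length(vars), nPatients, replace = TRUE)
        counts <- matrix(5L + stats::rpois(nPatients * length(vars), 2),
                         nPatients, length(vars))
        counts[cbind(which(!complete), shortVar[!complete])] <- 4L
        perVar <- lapply(seq_along(vars), function(v) {
            nv <- counts[, v]
            caseRep <- rep(case, nv)
            data.frame(
                patient_id = rep(ids, nv),
                variable = vars[v],
                time = sequence(nv),
                value = stats::rnorm(sum(nv),
                                     mu[v] + caseRep * effectSize * sd[v],
                                     sd[v]),
                stringsAsFactors = FALSE)
        })
        events <- do.call(rbind, perVar)
        events <- events[order(events$patient_id, events$variable,
                               events$time), , drop = FALSE]
        rownames(events) <- NULL
        hf <- heartFailureCodes()
        diagnoses <- data.frame(
            patient_id = ids,
            code = ifelse(case == 1L, sample(hf, nPatients, replace = TRUE),
                          "401.9"),
            stringsAsFactors = FALSE)
        list(events = events, diagnoses = diagnoses,
             labels = stats::setNames(case, ids))
    })
}
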