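#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' Longitudinal cohort of participant records
#'
#' A \code{Cohort} holds one record per participant: a fixed visit schedule,
#' a fixed ordered set of variables measured at every visit (for a
#' blood-pressure trial: systolic BP in mmHg, diastolic BP in mmHg and the
#' prescribed medication count), and a two-level group label per participant
#' (the randomised treatment arm, or case/control status for EHR-derived
#' cohorts). It extends \linkS4class{SummarizedExperiment}: the assay is the
#' feature-by-participant matrix with one feature per (visit, variable) pair
#' in variable-major order (all visits of the first variable, then the
#' second, ...), \code{colData} carries the arm factor, and \code{rowData}
#' maps features back to (variable, visit).
#'
#' Missing measurements are representable as \code{NA} so that
#' completeness filters can operate; all simulation and generation code in
#' this package produces complete records.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [Cohort()], [filterComplete()], [readCohort()]
#' @export
setClass("Cohort", contains = "SummarizedExperiment")

setValidity("Cohort", function(object) {
    msgs <- character()
    cd <- colData(object)
    if (!"arm" %in% colnames(cd)) {
        msgs <- c(msgs, "colData must contain an 'arm' column")
    } else if (!is.factor(cd$arm) || nlevels(cd$arm) != 2L) {
        msgs <- c(msgs, "'arm' must be a factor with exactly 2 levels")
    }
    rd <- rowData(object)
    if (!all(c("variable", "visit") %in% colnames(rd))) {
        msgs <- c(msgs, "rowData must contain 'variable' and 'visit'")
    }
    md <- metadata(object)
    if (is.null(md$visits) || is.null(md$variables)) {
        msgs <- c(msgs, "metadata must record 'visits' and 'variables'")
    } else if (all(c("variable", "visit") %in% colnames(rd))) {
        want_var <- rep(md$variables, each = length(md$visits))
        want_vis <- rep(md$visits, times = length(md$variables))
        if (nrow(object) != length(want_var) ||
            !identical(as.character(rd$variable), want_var) ||
            !identical(as.character(rd$visit), want_vis)) {
            msgs <- c(msgs, "features must be variable-major over (variables x visits)")
        }
    }
    if (!is.null(colnames(object)) && anyDuplicated(colnames(object))) {
        msgs <- c(msgs, "participant ids must be unique")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a Cohort
#'
#' @param values numeric matrix, participants in rows, one column per
#'   (visit, variable) pair in variable-major order (all visits of
#'   \code{variables[1]} first). \code{NA} marks a missing measurement.
#' @param arm character or factor of group labels, one per participant;
#'   coerced to a two-level factor (level order taken from \code{levels} if
#'   given, else sorted with \code{"standard"} before \code{"intensive"}
#'   when those are the labels).
#' @param visits ordered character vector of visit labels.
#' @param variables ordered character vector of variable names.
#' @param ids character vector of unique participant ids; autogenerated when
#'   \code{NULL}.
#' @param levels optional explicit arm level order.
#' @return a \linkS4class{Cohort}.
#' @examples
#' m <- matrix(rnorm(2 * 6), nrow = 2)
#' Cohort(m, arm = c("standard", "intensive"),
#'        visits = c("RZ", "1M"), variables = c("SBP", "DBP", "MEDS"))
#' @export
Cohort <- function(values, arm, visits, variables, ids = NULL, levels = NULL) {
    values <- as.matrix(values)
    if (nrow(values) != length(arm)) {
        stop("'arm' must have one label per row of 'values'")
    }
    p <- length(visits) * length(variables)
    if (ncol(values) != p) {
        stop(sprintf("'values' has %d columns; schedule implies %d",
                     ncol(values), p))
    }
    if (is.null(levels)) {
        u <- unique(as.character(arm))
        levels <- if (setequal(u, c("standard", "intensive"))) {
            c("standard", "intensive")
        } else if (is.factor(arm)) levels(arm) else sort(u)
    }
    arm <- factor(as.character(arm), levels = levels)
    if (anyNA(arm)) stop("arm labels outside declared levels")
    if (is.null(ids)) ids <- sprintf("P%05d", seq_len(nrow(values)))
    feat_var <- rep(variables, each = length(visits))
    feat_vis <- rep(visits, times = length(variables))
    assay <- t(values)
    rownames(assay) <- paste(feat_vis, feat_var, sep = "_")
    colnames(assay) <- ids
    se <- SummarizedExperiment(
        assays = SimpleList(values = assay),
        rowData = DataFrame(variable = feat_var, visit = feat_vis),
        colData = DataFrame(arm = arm, row.names = ids))
    md <- list(visits = as.character(visits),
               variables = as.character(variables))
    se@metadata <- md
    new("Cohort", se)
}

#' GAN training configuration
#'
#' Hyperparameters for [trainAcgan()]. \code{lotSize} is the expected number
#' of real participants per discriminator update (the "lot"); under private
#' training the sampling rate q = lotSize / n drives privacy amplification.
#' \code{clipNorm} is the per-participant gradient-norm bound C and
#' \code{noiseMultiplier} the Gaussian noise scale sigma, so each lot's
#' summed gradient receives noise of standard deviation sigma * C.
#'
#' @export
setClass("TrainConfig", representation(
    latentDim = "integer", lotSize = "integer", epochs = "integer",
    learningRate = "numeric", gLearningRate = "numeric",
    clipNorm = "numeric", noiseMultiplier = "numeric",
    private = "logical", seed = "integer", checkpointEvery = "integer",
    embedDim = "integer", hidden = "integer"))

setValidity("TrainConfig", function(object) {
    msgs <- character()
    if (object@lotSize < 1L) msgs <- c(msgs, "lotSize must be >= 1")
    if (object@epochs < 0L) msgs <- c(msgs, "epochs must be >= 0")
    if (object@clipNorm <= 0) msgs <- c(msgs, "clipNorm must be > 0")
    if (object@noiseMultiplier < 0) msgs <- c(msgs, "noiseMultiplier must be >= 0")
    if (object@private && object@noiseMultiplier == 0) {
        msgs <- c(msgs, "private training requires noiseMultiplier > 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' @param latentDim dimension of the generator's noise input z.
#' @param lotSize expected lot size L (participants per discriminator step).
#' @param epochs training epochs; each epoch makes ceiling(n / L)
#'   discriminator steps.
#' @param learningRate Adam step size for the discriminator (applied to the
#'   privatised gradient in private mode -- post-processing of the
#'   clip-and-noise mechanism).
#' @param gLearningRate Adam step size for the generator.
#' @param clipNorm per-participant gradient clipping bound C (mmHg-free,
#'   applies to the global gradient 2-norm).
#' @param noiseMultiplier noise scale sigma; Gaussian noise sd sigma * C is
#'   added to each lot's clipped gradient sum when \code{private}.
#' @param private train the discriminator with DP-SGD.
#' @param seed integer seed controlling all training randomness.
#' @param checkpointEvery keep a generator checkpoint every this many epochs.
#' @param embedDim dimension of the learned arm embedding.
#' @param hidden hidden-layer width of both networks.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(latentDim = 100L, lotSize = 60L, epochs = 1000L,
                        learningRate = 2e-4, gLearningRate = 2e-4,
                        clipNorm = 1, noiseMultiplier = 5, private = TRUE,
                        seed = 1L, checkpointEvery = 10L,
                        embedDim = 8L, hidden = 128L) {
    new("TrainConfig",
        latentDim = as.integer(latentDim), lotSize = as.integer(lotSize),
        epochs = as.integer(epochs), learningRate = learningRate,
        gLearningRate = gLearningRate, clipNorm = clipNorm,
        noiseMultiplier = noiseMultiplier, private = private,
        seed = as.integer(seed), checkpointEvery = as.integer(checkpointEvery),
        embedDim = as.integer(embedDim), hidden = as.integer(hidden))
}

#' Generator / discriminator network
#'
#' Parameters of one of the two AC-GAN networks, as a named list of weight
#' matrices and bias vectors, plus an architecture descriptor. The generator
#' maps (z, arm embedding) to a normalised participant matrix through two
#' ReLU hidden layers and a tanh output; the discriminator maps a normalised
#' participant record through two leaky-ReLU hidden layers to a real/fake
#' source score and an arm-probability head.
#'
#' @slot role \code{"generator"} or \code{"discriminator"}.
#' @slot params named list of numeric matrices/vectors.
#' @slot arch named list describing layer sizes and activations.
#' @export
setClass("GanModel", representation(
    role = "character", params = "list", arch = "list"))

setValidity("GanModel", function(object) {
    if (!object@role %in% c("generator", "discriminator")) {
        return("role must be 'generator' or 'discriminator'")
    }
    TRUE
})

#' Moments-accountant ledger
#'
#' Tracks the cumulative log moment alpha(lambda) of the privacy-loss random
#' variable of the subsampled Gaussian mechanism with sampling rate q and
#' noise multiplier sigma, over the discriminator steps taken so far. Log
#' moments add across steps, and the ledger converts to (epsilon, delta)
#' statements via the standard tail bound.
#'
#' @slot q Poisson sampling rate of the lot (L / n).
#' @slot sigma noise multiplier.
#' @slot steps number of noisy gradient steps taken on real data.
#' @slot lambdas integer moment orders evaluated.
#' @slot stepLogMoments per-step log moment alpha_step(lambda).
#' @slot logMoments accumulated log moments, \code{steps * stepLogMoments}.
#' @seealso [momentsLedger()], [deltaAtEpsilon()], [epsilonAtDelta()]
#' @export
setClass("MomentsLedger", representation(
    q = "numeric", sigma = "numeric", steps = "numeric",
    lambdas = "integer", stepLogMoments = "numeric", logMoments = "numeric"))

setValidity("MomentsLedger", function(object) {
    msgs <- character()
    if (object@q < 0 || object@q > 1) msgs <- c(msgs, "q must be in [0, 1]")
    if (object@sigma < 0) msgs <- c(msgs, "sigma must be >= 0")
    if (object@steps < 0) msgs <- c(msgs, "steps must be >= 0")
    if (length(object@logMoments) != length(object@lambdas)) {
        msgs <- c(msgs, "logMoments length must match lambdas")
    }
    if (length(msgs)) msgs else TRUE
})

#' An (epsilon, delta) differential-privacy budget
#'
#' epsilon bounds the log-scale shift any single participant can induce in
#' the output distribution; delta is the probability with which that bound
#' may fail. Budgets compose additively (basic composition).
#'
#' @slot epsilon privacy loss, >= 0.
#' @slot delta failure probability, in [0, 1].
#' @seealso [privacyBudget()], [composeBudgets()]
#' @export
setClass("PrivacyBudget", representation(epsilon = "numeric", delta = "numeric"))

setValidity("PrivacyBudget", function(object) {
    msgs <- character()
    if (object@epsilon < 0) msgs <- c(msgs, "epsilon must be >= 0")
    if (object@delta < 0 || object@delta > 1) msgs <- c(msgs, "delta must be in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' @param epsilon privacy loss, >= 0.
#' @param delta failure probability in [0, 1].
#' @rdname PrivacyBudget-class
#' @export
privacyBudget <- function(epsilon, delta) {
    new("PrivacyBudget", epsilon = as.numeric(epsilon), delta = as.numeric(delta))
}

#' A generator snapshot taken during training
#'
#' @slot epoch epoch index at which the snapshot was taken.
#' @slot generator the \linkS4class{GanModel} generator snapshot.
#' @slot ledger the accountant state at snapshot time.
#' @slot utility downstream-task utility in [0, 1], filled by
#'   [scoreCheckpoints()]; \code{NA} until scored.
#' @export
setClass("Checkpoint", representation(
    epoch = "integer", generator = "GanModel",
    ledger = "MomentsLedger", utility = "numeric"))
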