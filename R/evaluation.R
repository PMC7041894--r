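# Utility-evaluation suite comparing a real cohort with a synthetic one:
# correlation structure, summary statistics, the medication-titration
# decision rate, train-on-synthetic/test-on-real (TSTR) classification, and
# concordance of fitted model coefficients.

#' Pairwise Pearson correlation across all (visit, variable) columns
#'
#' Columns are ordered variable-major (all visits of the first variable,
#' then the next), the layout used for correlation-structure heatmaps.
#' Zero-variance columns yield correlation 0 with a warning.
#'
#' @param x a \linkS4class{Cohort}.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwisePearson <- function(x) {
    m <- participantMatrix(x)
    if (nrow(m) < 3L) stop("need at least 3 records")
    sds <- apply(m, 2, stats::sd)
    cc <- suppressWarnings(stats::cor(m))
    if (any(sds == 0)) {
        warning(sprintf("%d zero-variance column(s); correlations set to 0",
                        sum(sds == 0)))
        cc[sds == 0, ] <- 0
        cc[, sds == 0] <- 0
    }
    diag(cc) <- 1
    cc
}

#' Spearman similarity of two correlation structures
#'
#' Rank correlation between the strictly-lower-triangle entries (diagonal
#' excluded) of two correlation matrices -- how faithfully a synthetic
#' cohort reproduces the real cohort's dependence structure.
#'
#' @param matA,matB square matrices of identical dimension.
#' @return list with \code{rho} and \code{p} (unadjusted).
#' @export
structureSimilarity <- function(matA, matB) {
    if (!all(dim(matA) == dim(matB))) stop("matrices must share dimensions")
    va <- matA[lower.tri(matA)]
    vb <- matB[lower.tri(matB)]
    ct <- suppressWarnings(
        stats::cor.test(va, vb, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Per-arm summary statistics
#'
#' Mean and SD of every variable at every visit, within each arm.
#'
#' @param x a \linkS4class{Cohort}.
#' @return data.frame (arm, variable, visit, mean, sd). Empty arms are
#'   omitted with a warning.
#' @export
summaryStats <- function(x) {
    m <- participantMatrix(x)
    arm <- armLabels(x)
    rd <- rowData(x)
    out <- list()
    for (a in levels(arm)) {
        rows <- arm == a
        if (!any(rows)) {
            warning(sprintf("arm '%s' is empty and was omitted", a))
            next
        }
        sub <- m[rows, , drop = FALSE]
        out[[a]] <- data.frame(
            arm = a,
            variable = as.character(rd$variable),
            visit = as.character(rd$visit),
            mean = colMeans(sub),
            sd = apply(sub, 2, stats::sd),
            row.names = NULL)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Medication-addition rate above the systolic goal
#'
#' The proportion of visit transitions at which a medication was added,
#' among transitions whose starting SBP exceeded the participant's arm goal
#' (120 mmHg intensive / 140 mmHg standard by default). Transition-level
#' counting: the denominator is every above-goal transition, the numerator
#' those where the next visit's medication count is strictly larger.
#'
#' @param x a \linkS4class{Cohort} with SBP and MEDS variables and at least
#'   2 visits.
#' @param goals named mmHg goals, one per arm level.
#' @return list with \code{overall}, per-arm rates \code{perArm}, and the
#'   transition \code{counts}. An empty denominator yields \code{NA}, not 0.
#' @export
medAdditionRate <- function(x, goals = c(standard = 140, intensive = 120)) {
    if (length(visitSchedule(x)) < 2L) stop("need at least 2 visits")
    sbp <- variableMatrix(x, "SBP")
    meds <- variableMatrix(x, "MEDS")
    arm <- as.character(armLabels(x))
    if (!all(levels(armLabels(x)) %in% names(goals))) {
        stop("goals must name every arm level")
    }
    nv <- ncol(sbp)
    above <- sbp[, -nv, drop = FALSE] > goals[arm]
    added <- meds[, -1L, drop = FALSE] > meds[, -nv, drop = FALSE]
    rate <- function(rows) {
        den <- sum(above[rows, ])
        if (den == 0L) return(NA_real_)
        sum(added[rows, ] & above[rows, ]) / den
    }
    perArm <- vapply(levels(armLabels(x)), function(a) rate(arm == a),
                     numeric(1))
    list(overall = rate(rep(TRUE, nrow(sbp))), perArm = perArm,
         counts = c(aboveGoal = sum(above),
                    additions = sum(added & above)))
}

aurocOf <- function(labels, scores) {
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
}

#' Train-on-X, test-on-real transfer evaluation
#'
#' Fits the named classifiers to predict the arm label from the flattened,
#' identically normalised participant features of \code{train}, and scores
#' each by AUROC on the same held-out real \code{test} cohort. Training on
#' a synthetic cohort and comparing with models trained on the real cohort
#' (same test set) measures how much analysis-relevant signal the synthetic
#' data retains. Coefficient vectors are returned for the linear models and
#' importances for the forest, for concordance analysis.
#'
#' @param train training \linkS4class{Cohort} (real or synthetic).
#' @param test held-out real \linkS4class{Cohort}.
#' @param models subset of \code{"logistic_regression"}, \code{"svm"},
#'   \code{"random_forest"}, \code{"nearest_neighbors"}.
#' @param ranges shared normalisation ranges (fixed, so real and synthetic
#'   features are on identical scales and coefficients comparable).
#' @param seed integer seed fixed before each stochastic fit.
#' @return named list per model: \code{auroc} and \code{coefficients}
#'   (\code{NULL} for nearest neighbours).
#' @export
transferLearningEval <- function(train, test,
                                 models = c("logistic_regression", "svm",
                                            "random_forest",
                                            "nearest_neighbors"),
                                 ranges = defaultRanges(cohortVariables(train)),
                                 seed = 1L) {
    models <- match.arg(models, several.ok = TRUE)
    Xtr <- normalizeCohort(train, ranges)
    Xte <- normalizeCohort(test, ranges)
    ytr <- as.integer(armLabels(train)) - 1L
    yte <- as.integer(armLabels(test)) - 1L
    if (length(unique(ytr)) < 2L) stop("training labels are single-class")
    res <- list()
    for (mod in models) {
        res[[mod]] <- withSeed(deriveSeed(seed, match(mod, models)), {
            switch(mod,
                logistic_regression = {
                    df <- data.frame(y = ytr, Xtr)
                    fit <- suppressWarnings(
                        stats::glm(y ~ ., data = df, family = stats::binomial()))
                    sc <- suppressWarnings(stats::predict(
                        fit, newdata = data.frame(Xte), type = "link"))
                    list(auroc = aurocOf(yte, sc),
                         coefficients = stats::coef(fit)[-1])
                },
                svm = {
                    fit <- e1071::svm(Xtr, factor(ytr), kernel = "linear",
                                      scale = FALSE)
                    dvm <- attr(stats::predict(fit, Xte,
                                               decision.values = TRUE),
                                "decision.values")
                    dv <- dvm[, 1]
                    # e1071 labels the column "A/B": positive favours A
                    if (colnames(dvm)[1] == "0/1") dv <- -dv
                    w <- drop(t(fit$coefs) %*% fit$SV)
                    list(auroc = aurocOf(yte, dv), coefficients = w)
                },
                random_forest = {
                    fit <- randomForest::randomForest(Xtr, factor(ytr),
                                                      ntree = 200)
                    sc <- stats::predict(fit, Xte, type = "prob")[, "1"]
                    list(auroc = aurocOf(yte, sc),
                         coefficients = drop(randomForest::importance(fit)))
                },
                nearest_neighbors = {
                    pred <- class::knn(Xtr, Xte, factor(ytr), k = 9L,
                                       prob = TRUE)
                    pw <- attr(pred, "prob")
                    sc <- ifelse(pred == "1", pw, 1 - pw)
                    list(auroc = aurocOf(yte, sc), coefficients = NULL)
                })
        })
    }
    res
}

#' Concordance of coefficient / importance vectors
#'
#' Pearson and Spearman correlation between the coefficient (or importance)
#' vectors of a model trained on real data and the same model trained on
#' synthetic data: do the two models rely on the same features?
#'
#' @param vecReal,vecSynthetic equal-length numeric vectors.
#' @return list with \code{pearson} (r, p) and \code{spearman} (rho, p),
#'   p-values unadjusted.
#' @export
coefficientConcordance <- function(vecReal, vecSynthetic) {
    if (length(vecReal) != length(vecSynthetic)) {
        stop("vectors must have equal length")
    }
    pe <- stats::cor.test(vecReal, vecSynthetic, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(vecReal, vecSynthetic,
                                           method = "spearman", exact = FALSE))
    list(pearson = list(r = unname(pe$estimate), p = pe$p.value),
         spearman = list(rho = unname(sp$estimate), p = sp$p.value))
}

#' Mann-Whitney U comparison of two score samples
#'
#' Rank-sum test for whether two sets of scores (e.g. blinded realism
#' ratings of real and synthetic records) differ in distribution. Reports
#' the U statistic of the first sample. The two-sided p-value uses exact
#' enumeration of all label assignments when the combined sample size is at
#' most 12, and the tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param scoresA,scoresB numeric score vectors, non-empty.
#' @return list with \code{U}, \code{p} and \code{method}.
#' @export
scoreComparison <- function(scoresA, scoresB) {
    if (length(scoresA) == 0L || length(scoresB) == 0L) {
        stop("score lists must be non-empty")
    }
    n1 <- length(scoresA); n2 <- length(scoresB)
    pooled <- c(scoresA, scoresB)
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (n1 + n2 <= 12L) {
        combs <- utils::combn(n1 + n2, n1)
        Us <- apply(combs, 2, function(ix) {
            sum(r[ix]) - n1 * (n1 + 1) / 2
        })
        pLess <- mean(Us <= U)
        pGreater <- mean(Us >= U)
        p <- min(1, 2 * min(pLess, pGreater))
        method <- "exact enumeration"
    } else {
        n <- n1 + n2
        ties <- table(r)
        mu <- n1 * n2 / 2
        sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        z <- U - mu
        z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)
        p <- 2 * stats::pnorm(-abs(z))
        method <- "normal approximation with tie correction"
    }
    list(U = U, p = p, method = method)
}

#' Full real-vs-synthetic evaluation report
#'
#' Runs the whole suite: correlation matrices and their Spearman structure
#' similarity, per-arm summary tables, medication-addition rates, TSTR
#' classification of every requested model trained on real and on synthetic
#' data (same real test set), and coefficient concordance per model.
#'
#' @param real real training \linkS4class{Cohort}.
#' @param synthetic synthetic \linkS4class{Cohort}.
#' @param test held-out real \linkS4class{Cohort} for the transfer task;
#'   \code{NULL} skips it.
#' @param models classifiers for the transfer task.
#' @param goals arm goals for the medication-addition rate; \code{NULL}
#'   skips that section (e.g. for EHR cohorts).
#' @param ranges shared normalisation ranges.
#' @param seed integer seed.
#' @return an \code{EvaluationReport} list; see [writeReport()].
#' @export
evaluateCohorts <- function(real, synthetic, test = NULL,
                            models = c("logistic_regression", "svm",
                                       "random_forest", "nearest_neighbors"),
                            goals = c(standard = 140, intensive = 120),
                            ranges = defaultRanges(cohortVariables(real)),
                            seed = 1L) {
    corReal <- pairwisePearson(real)
    corSyn <- pairwisePearson(synthetic)
    rep <- list(
        correlation = list(real = corReal, synthetic = corSyn),
        structureSimilarity = structureSimilarity(corReal, corSyn),
        summary = list(real = summaryStats(real),
                       synthetic = summaryStats(synthetic)))
    if (!is.null(goals)) {
        rep$medAddition <- list(real = medAdditionRate(real, goals),
                                synthetic = medAdditionRate(synthetic, goals))
    }
    if (!is.null(test)) {
        tr <- transferLearningEval(real, test, models, ranges, seed)
        ts <- transferLearningEval(synthetic, test, models, ranges, seed)
        rep$transfer <- list(
            auroc = data.frame(
                model = models,
                trainedOnReal = vapply(models, function(m) tr[[m]]$auroc,
                                       numeric(1)),
                trainedOnSynthetic = vapply(models, function(m) ts[[m]]$auroc,
                                            numeric(1)),
                row.names = NULL))
        rep$concordance <- list()
        for (m in models) {
            if (!is.null(tr[[m]]$coefficients)) {
                rep$concordance[[m]] <- coefficientConcordance(
                    tr[[m]]$coefficients, ts[[m]]$coefficients)
            }
        }
    }
    class(rep) <- "EvaluationReport"
    rep
}

#' Serialise / restore an evaluation report
#'
#' JSON round trip is lossless for the report's numeric content.
#'
#' @param report an \code{EvaluationReport}.
#' @param path file path.
#' @export
writeReport <- function(report, path) {
    jsonlite::write_json(unclass(report), path, digits = NA, pretty = TRUE,
                         auto_unbox = TRUE, na = "null")
    invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
    rep <- jsonlite::read_json(path, simplifyVector = TRUE)
    rep$correlation <- lapply(rep$correlation, as.matrix)
    class(rep) <- "EvaluationReport"
    rep
}
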