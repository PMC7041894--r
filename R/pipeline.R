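# End-to-end orchestration: simulate (or read) -> split -> train -> score ->
# select -> pooled generate -> evaluate, driven by one YAML/list config with
# a single seed fanned out deterministically to the stages.

defaultPipelineConfig <- function() {
    list(
        simulate = list(nParticipants = 500L),
        split = list(nTrain = 400L),
        train = list(epochs = 20L, lotSize = 50L, private = FALSE,
                     noiseMultiplier = 0, checkpointEvery = 5L),
        select = list(k = 2L, epsilonPerSelection = 0.05,
                      nSynthetic = 200L),
        generate = list(n = 500L, armMix = 0.5),
        evaluate = list(models = c("logistic_regression", "random_forest")))
}

mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
            mergeConfig(base[[nm]], override[[nm]])
        } else {
            override[[nm]]
        }
    }
    base
}

#' Run the full synthesis pipeline
#'
#' Executes simulate -> split -> train -> select -> generate -> evaluate as
#' configured and writes every artifact (cohorts as CSV, report and
#' manifest as JSON) under \code{outDir}. The manifest records the config
#' snapshot, the derived per-stage seeds, checkpoint epochs, the composed
#' privacy budget and all output paths, so a run can be reproduced
#' bit-for-bit from it (single-threaded floating point caveats aside).
#'
#' @param config list or YAML file path; entries override
#'   the built-in smoke-test defaults (sections \code{simulate},
#'   \code{split}, \code{train}, \code{select}, \code{generate},
#'   \code{evaluate}; an optional \code{input} section with a \code{path}
#'   reads a cohort CSV instead of simulating).
#' @param outDir output directory, created if needed.
#' @param seed global integer seed.
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = list(), outDir = tempfile("dpsynth_run_"),
                        seed = 1L) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- mergeConfig(defaultPipelineConfig(), config)
    tc <- do.call(trainConfig, c(cfg$train,
                                 list(seed = deriveSeed(seed, 2L))))
    validObject(tc)  # reject inconsistent private settings before any work
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seeds <- list(simulate = deriveSeed(seed, 1L), train = deriveSeed(seed, 2L),
                  select = deriveSeed(seed, 3L), generate = deriveSeed(seed, 4L),
                  evaluate = deriveSeed(seed, 5L), split = deriveSeed(seed, 6L))

    cohort <- if (!is.null(cfg$input$path)) {
        readCohort(cfg$input$path)
    } else {
        simulateTrial(do.call(trialSimParams,
                              c(cfg$simulate, list(seed = seeds$simulate))))
    }
    cohort <- filterComplete(cohort)
    sp <- splitTrainTest(cohort, cfg$split$nTrain, seed = seeds$split)
    trainPath <- file.path(outDir, "train.csv")
    testPath <- file.path(outDir, "test.csv")
    writeCohort(sp$train, trainPath)
    writeCohort(sp$test, testPath)

    run <- trainAcgan(sp$train, tc)
    scored <- scoreCheckpoints(run$checkpoints, sp$train,
                               nSynthetic = cfg$select$nSynthetic,
                               seed = seeds$select)
    utilities <- vapply(scored, function(ck) ck@utility, numeric(1))
    sel <- selectModels(utilities, selectionConfig(
        k = cfg$select$k,
        epsilonPerSelection = cfg$select$epsilonPerSelection,
        sensitivity = 1 / nParticipants(sp$train),
        seed = seeds$select))
    chosen <- scored[sel$selected]

    synthetic <- poolGenerate(chosen, cfg$generate$n,
                              armMix = cfg$generate$armMix,
                              seed = seeds$generate)
    synPath <- file.path(outDir, "synthetic.csv")
    writeCohort(synthetic, synPath)

    trainingBudget <- if (tc@private) {
        privacyBudget(epsilonAtDelta(run$ledger, 1e-5), 1e-5)
    } else {
        privacyBudget(Inf, 0)
    }
    budget <- if (tc@private) {
        composeBudgets(list(trainingBudget, sel$budget))
    } else {
        sel$budget
    }

    report <- evaluateCohorts(sp$train, synthetic, sp$test,
                              models = cfg$evaluate$models,
                              seed = seeds$evaluate)
    reportPath <- file.path(outDir, "report.json")
    writeReport(report, reportPath)

    manifest <- list(
        config = cfg, seed = seed, seeds = seeds,
        checkpointEpochs = vapply(scored, function(ck) ck@epoch, integer(1)),
        selectedEpochs = vapply(chosen, function(ck) ck@epoch, integer(1)),
        budget = list(epsilon = if (is.finite(budget@epsilon))
                          budget@epsilon else "unbounded",
                      delta = budget@delta,
                      training = list(
                          epsilon = if (is.finite(trainingBudget@epsilon))
                              trainingBudget@epsilon else "unbounded",
                          delta = trainingBudget@delta),
                      selection = list(epsilon = sel$budget@epsilon,
                                       delta = sel$budget@delta)),
        paths = list(train = trainPath, test = testPath,
                     synthetic = synPath, report = reportPath))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    invisible(manifest)
}
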