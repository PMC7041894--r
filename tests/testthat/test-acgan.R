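test_that("generator forward pass honours the shape contract", {
    gen <- untrainedGenerator()
    z <- matrix(rnorm(7 * 100), 7, 100)
    y <- generatorForward(gen, z, rep("standard", 7))
    expect_equal(dim(y), c(7L, 36L))
    expect_true(all(y >= -1 & y <= 1))
    expect_identical(generatorForward(gen, z, rep("standard", 7)), y)
    expect_error(generatorForward(gen, z[, 1:10], rep("standard", 7)),
                 "latentDim")
    expect_error(generatorForward(gen, z, rep("standard", 3)), "one arm")
})

test_that("arm conditioning enters through the embedding", {
    gen <- untrainedGenerator()
    z0 <- matrix(0, 4, 100)
    ya <- generatorForward(gen, z0, rep("standard", 4))
    yb <- generatorForward(gen, z0, rep("intensive", 4))
    expect_false(isTRUE(all.equal(ya, yb)))
})

test_that("discriminator forward pass scores and bounds", {
    set.seed(3)
    disc <- dpsynth:::initDiscriminator(36L, 32L)
    x <- matrix(runif(5 * 36, -1, 1), 5, 36)
    out <- discriminatorForward(disc, x)
    expect_equal(nrow(out), 5L)
    expect_true(all(is.finite(out$source)))
    expect_true(all(out$armProb >= 0 & out$armProb <= 1))
    expect_identical(discriminatorForward(disc, x), out)
    expect_error(discriminatorForward(disc, x[, 1:12]), "expects")
})

test_that("losses reduce to closed forms at indifference", {
    disc <- dpsynth:::initDiscriminator(6L, 4L)
    disc@params <- lapply(disc@params, function(p) p * 0)  # all logits 0
    x <- matrix(runif(12, -1, 1), 2, 6)
    l <- acganLosses(disc, x, x, c("standard", "intensive"),
                     c("intensive", "standard"))
    # each head contributes ln 2 per sample on both batches
    expect_equal(l$dLoss, 4 * log(2))
    expect_equal(l$gLoss, 2 * log(2))
    expect_error(acganLosses(disc, x[0, , drop = FALSE], x,
                             character(0), c("a", "b")), "non-empty")
})

test_that("a class head that contradicts the label pays more than ln 2", {
    disc <- dpsynth:::initDiscriminator(6L, 4L)
    disc@params <- lapply(disc@params, function(p) p * 0)
    # bias the arm head towards level 2 while labelling level 1
    disc@params$ba <- 2
    x <- matrix(0.1, 3, 6)
    l <- acganLosses(disc, x, x, rep("standard", 3), rep("standard", 3))
    # hand value: bce(logit = 2, target = 0) = log(1 + e^2)
    expect_equal(l$gLoss, log(2) + log1p(exp(2)))
    expect_gt(l$gLoss - log(2), log(2))
})

test_that("training counts ledger steps and checkpoints as configured", {
    co <- simulateTrial(trialSimParams(nParticipants = 150, seed = 5))
    cfg <- trainConfig(epochs = 4, lotSize = 40, private = TRUE,
                       noiseMultiplier = 5, checkpointEvery = 2, seed = 6)
    run <- trainAcgan(co, cfg)
    expect_equal(run$ledger@steps, 4 * ceiling(150 / 40))
    expect_equal(vapply(run$checkpoints, function(ck) ck@epoch, integer(1)),
                 c(2L, 4L))
    # checkpoint epochs strictly increasing, ledgers nested
    expect_lt(run$checkpoints[[1]]@ledger@steps,
              run$checkpoints[[2]]@ledger@steps)
    expect_error(trainAcgan(co, trainConfig(lotSize = 500, private = FALSE,
                                            noiseMultiplier = 0)),
                 "exceeds")
    expect_error(trainConfig(private = TRUE, noiseMultiplier = 0),
                 "noiseMultiplier")
})

test_that("zero epochs yield an empty run with a zeroed ledger", {
    co <- simulateTrial(trialSimParams(nParticipants = 60, seed = 7))
    run <- trainAcgan(co, trainConfig(epochs = 0, lotSize = 20,
                                      private = FALSE, noiseMultiplier = 0))
    expect_length(run$checkpoints, 0)
    expect_equal(run$ledger@steps, 0)
    expect_equal(deltaAtEpsilon(run$ledger, 1), 0)
})

test_that("training is reproducible for a fixed seed", {
    co <- simulateTrial(trialSimParams(nParticipants = 100, seed = 8))
    cfg <- trainConfig(epochs = 2, lotSize = 50, private = FALSE,
                       noiseMultiplier = 0, seed = 9, checkpointEvery = 1)
    a <- trainAcgan(co, cfg)
    b <- trainAcgan(co, cfg)
    expect_equal(a$generator@params, b$generator@params, tolerance = 0)
    expect_equal(a$history, b$history)
})

test_that("generation splits arms exactly, rounds counts, spares the ledger", {
    co <- simulateTrial(trialSimParams(nParticipants = 120, seed = 10))
    cfg <- trainConfig(epochs = 2, lotSize = 40, private = TRUE,
                       noiseMultiplier = 5, checkpointEvery = 1, seed = 11)
    run <- trainAcgan(co, cfg)
    ledgerBefore <- run$checkpoints[[2]]@ledger
    syn <- generateCohort(run$checkpoints[[2]], 500, armMix = 0.5, seed = 12)
    expect_equal(unname(table(armLabels(syn))["standard"]), 250)
    expect_equal(unname(table(armLabels(syn))["intensive"]), 250)
    meds <- variableMatrix(syn, "MEDS")
    expect_true(all(meds == round(meds) & meds >= 0 & meds <= 10))
    sbp <- variableMatrix(syn, "SBP")
    expect_true(all(sbp >= 60 & sbp <= 250))
    # post-processing: the stored ledger is untouched by generation
    expect_identical(run$checkpoints[[2]]@ledger, ledgerBefore)
    syn2 <- generateCohort(run$checkpoints[[2]], 500, armMix = 0.5, seed = 12)
    expect_identical(participantMatrix(syn), participantMatrix(syn2))
    expect_error(generateCohort(run$generator, 0), "> 0")
})

test_that("short adversarial training learns arm-conditional structure", {
    co <- simulateTrial(trialSimParams(nParticipants = 800, seed = 13))
    cfg <- trainConfig(epochs = 60, lotSize = 100, private = FALSE,
                       noiseMultiplier = 0, seed = 14, checkpointEvery = 30)
    run <- trainAcgan(co, cfg)
    syn <- generateCohort(run$generator, 600, seed = 15)
    # a classifier fit on REAL data recognises the requested arms of the
    # synthetic records at better than chance
    Xr <- normalizeCohort(co)
    Xs <- normalizeCohort(syn)
    df <- data.frame(y = as.integer(armLabels(co)) - 1L, Xr)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    p <- predict(fit, newdata = data.frame(Xs), type = "response")
    agree <- mean((p > 0.5) == (as.integer(armLabels(syn)) == 2L))
    expect_gt(agree, 0.6)
})
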