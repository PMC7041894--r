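test_that("pairwise Pearson matrix is symmetric with unit diagonal", {
    co <- simulateTrial(trialSimParams(nParticipants = 200, seed = 1))
    cc <- pairwisePearson(co)
    expect_equal(cc, t(cc))
    expect_equal(unname(diag(cc)), rep(1, 36))
    expect_true(all(cc >= -1 & cc <= 1))
})

test_that("perfectly coupled variables show unit cross-correlation", {
    set.seed(2)
    sbp <- matrix(rnorm(30 * 3, 140, 10), 30, 3)
    vals <- cbind(sbp, sbp, matrix(1, 30, 3))  # DBP identical to SBP
    co <- Cohort(vals, arm = rep(c("standard", "intensive"), 15),
                 visits = c("RZ", "1M", "2M"),
                 variables = c("SBP", "DBP", "MEDS"))
    expect_warning(cc <- pairwisePearson(co), "zero-variance")
    for (v in 1:3) expect_equal(unname(cc[v, v + 3]), 1)  # SBP_t vs DBP_t
    expect_equal(unname(cc[7, 8]), 0)  # constant MEDS columns zeroed
})

test_that("independent columns show near-zero off-diagonals", {
    set.seed(3)
    vals <- matrix(rnorm(10000 * 9), 10000, 9)
    co <- Cohort(vals, arm = rep(c("standard", "intensive"), 5000),
                 visits = c("RZ", "1M", "2M"),
                 variables = c("SBP", "DBP", "MEDS"))
    cc <- suppressWarnings(pairwisePearson(co))
    off <- cc[lower.tri(cc)]
    expect_lt(max(abs(off)), 0.04)
})

test_that("structure similarity is a rank statistic on lower triangles", {
    co <- simulateTrial(trialSimParams(nParticipants = 300, seed = 4))
    cc <- pairwisePearson(co)
    expect_equal(structureSimilarity(cc, cc)$rho, 1)
    # reversed rank order on a 3x3 pair: rho = -1
    a <- diag(3); b <- diag(3)
    a[lower.tri(a)] <- c(0.1, 0.5, 0.9)
    b[lower.tri(b)] <- c(0.8, 0.4, 0.2)
    expect_equal(structureSimilarity(a, b)$rho, -1)
    # hand-ranked toy: triangles (0.1, 0.5, 0.9) vs (0.3, 0.2, 0.8)
    # ranks (1,2,3) vs (2,1,3): rho = 1 - 6*(1+1+0)/(3*8) = 0.5
    b[lower.tri(b)] <- c(0.3, 0.2, 0.8)
    expect_equal(structureSimilarity(a, b)$rho, 0.5)
    expect_error(structureSimilarity(a, diag(4)), "dimensions")
})

test_that("summary statistics match hand arithmetic and mix consistently", {
    co <- toyCohort()
    st <- summaryStats(co)
    rz <- st[st$arm == "standard" & st$variable == "SBP" & st$visit == "RZ", ]
    expect_equal(rz$mean, mean(c(150, 135)))
    expect_equal(rz$sd, sd(c(150, 135)))
    # mixture identity: pooled mean is the count-weighted arm mean
    pooledRz <- mean(participantMatrix(co)[, "RZ_SBP"])
    arms <- table(armLabels(co))
    stRz <- st[st$variable == "SBP" & st$visit == "RZ", ]
    expect_equal(sum(stRz$mean * as.numeric(arms[stRz$arm])) / sum(arms),
                 pooledRz)
    # constant cohort: all SDs zero
    cc <- Cohort(matrix(5, 4, 9), arm = rep(c("standard", "intensive"), 2),
                 visits = c("RZ", "1M", "2M"),
                 variables = c("SBP", "DBP", "MEDS"))
    expect_true(all(summaryStats(cc)$sd == 0))
    # empty arm warns and is omitted
    oneArm <- Cohort(matrix(5, 2, 9), arm = c("standard", "standard"),
                     visits = c("RZ", "1M", "2M"),
                     variables = c("SBP", "DBP", "MEDS"),
                     levels = c("standard", "intensive"))
    expect_warning(stOne <- summaryStats(oneArm), "empty")
    expect_equal(unique(stOne$arm), "standard")
})

test_that("medication-addition rate counts above-goal transitions", {
    # P1 (standard): SBP (150, 145, 130), meds (1, 2, 2)
    # P2 (standard): SBP (135, 150, 150), meds (0, 0, 1)
    vals <- rbind(c(150, 145, 130, 80, 80, 80, 1, 2, 2),
                  c(135, 150, 150, 70, 70, 70, 0, 0, 1))
    co <- Cohort(vals, arm = c("standard", "standard"),
                 visits = c("RZ", "1M", "2M"),
                 variables = c("SBP", "DBP", "MEDS"),
                 levels = c("standard", "intensive"))
    r <- medAdditionRate(co)
    expect_equal(r$overall, 2 / 3)
    expect_equal(unname(r$counts["aboveGoal"]), 3)
    # always below goal: undefined, not zero
    low <- Cohort(rbind(c(110, 111, 112, 70, 70, 70, 1, 2, 3)),
                  arm = "standard", visits = c("RZ", "1M", "2M"),
                  variables = c("SBP", "DBP", "MEDS"),
                  levels = c("standard", "intensive"))
    expect_true(is.na(medAdditionRate(low)$overall))
    # constant medications: rate zero
    flat <- Cohort(rbind(c(150, 150, 150, 80, 80, 80, 2, 2, 2)),
                   arm = "standard", visits = c("RZ", "1M", "2M"),
                   variables = c("SBP", "DBP", "MEDS"),
                   levels = c("standard", "intensive"))
    expect_equal(medAdditionRate(flat)$overall, 0)
})

test_that("separable arms give AUROC 1 for every classifier", {
    set.seed(5)
    n <- 120
    arm <- rep(c("standard", "intensive"), n / 2)
    base <- matrix(rnorm(n * 12, 100, 2), n, 12)
    base[arm == "standard", 1:4] <- base[arm == "standard", 1:4] + 50
    vals <- cbind(base[, 1:4], base[, 5:8], matrix(2, n, 4))
    co <- Cohort(vals, arm = arm, visits = c("RZ", "1M", "2M", "3M"),
                 variables = c("SBP", "DBP", "MEDS"))
    sp <- splitTrainTest(co, 80, seed = 6)
    res <- transferLearningEval(sp$train, sp$test, seed = 7)
    for (m in names(res)) expect_equal(res[[m]]$auroc, 1.0)
    # determinism of the full suite
    res2 <- transferLearningEval(sp$train, sp$test, seed = 7)
    for (m in names(res)) expect_equal(res[[m]]$auroc, res2[[m]]$auroc)
})

test_that("shuffled labels give chance-level AUROC", {
    set.seed(8)
    n <- 2000
    vals <- matrix(rnorm(n * 36, 120, 10), n, 36)
    vals[, 25:36] <- matrix(runif(n * 12, 0, 10), n, 12)  # in-range med counts
    arm <- sample(rep(c("standard", "intensive"), n / 2))
    co <- Cohort(vals, arm = arm, visits = cohortSchema()$visits,
                 variables = cohortSchema()$variables)
    sp <- splitTrainTest(co, 1500, seed = 9)
    # normal tails stray past the physiologic ranges; clamping is intended
    res <- suppressWarnings(
        transferLearningEval(sp$train, sp$test,
                             c("logistic_regression", "svm"), seed = 10))
    for (m in names(res)) expect_lt(abs(res[[m]]$auroc - 0.5), 0.08)
})

test_that("single-class training labels are rejected", {
    co <- simulateTrial(trialSimParams(nParticipants = 40, pIntensive = 0,
                                       seed = 11))
    sp <- splitTrainTest(co, 30, seed = 12)
    expect_error(transferLearningEval(sp$train, sp$test), "single-class")
})

test_that("coefficient concordance reports both correlation flavours", {
    v <- c(0.3, -1.2, 0.8, 2.1, -0.4)
    cc <- coefficientConcordance(v, v)
    expect_equal(cc$pearson$r, 1)
    expect_equal(cc$spearman$rho, 1)
    cc2 <- coefficientConcordance(v, -v)
    expect_equal(cc2$pearson$r, -1)
    expect_equal(cc2$spearman$rho, -1)
    # length-5 toy against hand-computed Pearson r
    a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
    handR <- sum((a - 3) * (b - 3.2)) /
        sqrt(sum((a - 3)^2) * sum((b - 3.2)^2))
    expect_equal(coefficientConcordance(a, b)$pearson$r, handR)
    expect_error(coefficientConcordance(1:3, 1:4), "equal length")
})

test_that("Mann-Whitney U agrees with enumeration and wilcox.test", {
    # complete separation: first sample entirely below
    expect_equal(scoreComparison(c(1, 2, 3), c(4, 5, 6))$U, 0)
    # identical samples are indistinguishable
    same <- scoreComparison(c(1, 2, 3), c(1, 2, 3))
    expect_gt(same$p, 0.99)
    # brute-force pair counting: U = #{a > b} + 0.5 #{a = b}
    a <- c(1, 2, 3); b <- c(2, 3, 4)
    handU <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(scoreComparison(a, b)$U, handU)
    # tie-free exact p matches wilcox.test's exact distribution
    set.seed(13)
    for (i in 1:5) {
        x <- sample(100, 4); y <- sample(200, 5) + 0.5
        got <- scoreComparison(x, y)
        ref <- wilcox.test(x, y, exact = TRUE)
        expect_equal(got$U, unname(ref$statistic))
        expect_equal(got$p, ref$p.value)
    }
    # large-sample path matches wilcox.test's corrected normal approximation
    set.seed(14)
    x <- round(rnorm(30, 5, 2)); y <- round(rnorm(25, 6, 2))
    got <- scoreComparison(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_error(scoreComparison(numeric(0), 1:3), "non-empty")
})

test_that("evaluation reports serialise losslessly", {
    co <- simulateTrial(trialSimParams(nParticipants = 250, seed = 15))
    sp <- splitTrainTest(co, 200, seed = 16)
    syn <- generateCohort(untrainedGenerator(2), 200, seed = 17)
    rep <- evaluateCohorts(sp$train, syn, sp$test,
                           models = "logistic_regression", seed = 18)
    expect_s3_class(rep$transfer$auroc, "data.frame")
    path <- tempfile(fileext = ".json")
    writeReport(rep, path)
    back <- readReport(path)
    expect_equal(back$structureSimilarity$rho, rep$structureSimilarity$rho)
    expect_equal(unname(back$correlation$real),
                 unname(rep$correlation$real), tolerance = 1e-12)
    expect_equal(back$transfer$auroc$trainedOnReal,
                 rep$transfer$auroc$trainedOnReal)
    expect_equal(back$medAddition$real$overall, rep$medAddition$real$overall)
})
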