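test_that("cohort CSV round trip preserves records and arm labels", {
    path <- writeToyCsv(n = 3)
    co <- readCohort(path)
    expect_s4_class(co, "Cohort")
    expect_equal(nParticipants(co), 3L)
    expect_equal(visitSchedule(co), cohortSchema()$visits)
    path2 <- tempfile(fileext = ".csv")
    writeCohort(co, path2)
    co2 <- readCohort(path2)
    expect_equal(participantMatrix(co2), participantMatrix(co))
    expect_equal(as.character(armLabels(co2)), as.character(armLabels(co)))
})

test_that("arm labels parse case-insensitively", {
    path <- writeToyCsv(n = 3, armCase = TRUE)
    co <- readCohort(path)
    expect_true(all(as.character(armLabels(co)) %in%
                    c("standard", "intensive")))
})

test_that("schema violations are reported by name and position", {
    path <- writeToyCsv(n = 3)
    df <- read.csv(path, check.names = FALSE)
    df[["27M_SBP"]] <- NULL
    p2 <- tempfile(fileext = ".csv")
    write.csv(df, p2, row.names = FALSE, quote = FALSE)
    expect_error(readCohort(p2), "27M_SBP")

    df <- read.csv(path, check.names = FALSE)
    df[2, "RZ_DBP"] <- "oops"
    p3 <- tempfile(fileext = ".csv")
    write.csv(df, p3, row.names = FALSE, quote = FALSE)
    expect_error(readCohort(p3), "row 2.*RZ_DBP")
})

test_that("filterComplete keeps exactly the fully observed records", {
    co <- simulateTrial(trialSimParams(nParticipants = 5, seed = 3))
    m <- participantMatrix(co)
    m[2, "3M_SBP"] <- NA
    m[4, "3M_SBP"] <- NA
    holey <- Cohort(m, arm = armLabels(co), visits = visitSchedule(co),
                    variables = cohortVariables(co))
    kept <- filterComplete(holey)
    expect_equal(nParticipants(kept), 3L)
    expect_equal(participantIds(kept), participantIds(holey)[c(1, 3, 5)])
    # idempotent
    expect_equal(participantMatrix(filterComplete(kept)),
                 participantMatrix(kept))
    # no missingness: identity
    expect_equal(participantMatrix(filterComplete(co)), participantMatrix(co))
    expect_error(filterComplete(co, requiredVisits = 13), "exceeds")
    # partial requirement: record missing only a late visit survives an
    # early-visit filter
    m2 <- participantMatrix(co)
    m2[1, "27M_SBP"] <- NA
    h2 <- Cohort(m2, arm = armLabels(co), visits = visitSchedule(co),
                 variables = cohortVariables(co))
    expect_equal(nParticipants(filterComplete(h2, requiredVisits = 3)), 5L)
})

test_that("splitTrainTest partitions deterministically", {
    n <- 6502
    co <- Cohort(matrix(0, n, 36), arm = rep(c("standard", "intensive"),
                                             length.out = n),
                 visits = cohortSchema()$visits,
                 variables = cohortSchema()$variables)
    sp <- splitTrainTest(co, 6000, seed = 7)
    expect_equal(nParticipants(sp$train), 6000L)
    expect_equal(nParticipants(sp$test), 502L)
    expect_length(intersect(participantIds(sp$train),
                            participantIds(sp$test)), 0)
    expect_setequal(c(participantIds(sp$train), participantIds(sp$test)),
                    participantIds(co))
    sp2 <- splitTrainTest(co, 6000, seed = 7)
    expect_identical(participantIds(sp2$train), participantIds(sp$train))
    sp3 <- splitTrainTest(co, 6000, seed = 8)
    expect_false(identical(participantIds(sp3$train),
                           participantIds(sp$train)))
    expect_error(splitTrainTest(co, n), "smaller")
    sp0 <- splitTrainTest(co, 0, seed = 1)
    expect_equal(nParticipants(sp0$train), 0L)
    expect_equal(nParticipants(sp0$test), n)
})

test_that("normalisation is the declared affine map and round-trips", {
    co <- toyCohort()
    m <- normalizeCohort(co)
    expect_true(all(abs(m) <= 1))
    # midpoint of the SBP range maps to zero
    one <- Cohort(matrix(c(155, 155, 155, 90, 90, 90, 2, 2, 2), 1),
                  arm = "standard", visits = c("RZ", "1M", "2M"),
                  variables = c("SBP", "DBP", "MEDS"),
                  levels = c("standard", "intensive"))
    expect_equal(unname(normalizeCohort(one)[1, "RZ_SBP"]), 0)
    back <- denormalizeMatrix(normalizeCohort(co), arm = armLabels(co),
                              visits = visitSchedule(co),
                              variables = cohortVariables(co))
    cont <- grepl("SBP|DBP", colnames(participantMatrix(co)))
    expect_lt(max(abs(participantMatrix(back)[, cont] -
                      participantMatrix(co)[, cont])), 1e-9)
    # counts round-trip through the integer rounding rule
    expect_equal(participantMatrix(back)[, !cont],
                 participantMatrix(co)[, !cont])
})

test_that("denormalisation rounds counts and clamps to range", {
    m <- matrix(0, 1, 9)
    m[1, 7] <- 0.12            # MEDS, range (0,10): 5 + 0.12*5 = 5.6 -> 6
    m[1, 1] <- 3               # out-of-range normalised SBP clamps to max
    co <- denormalizeMatrix(m, arm = "standard",
                            visits = c("RZ", "1M", "2M"),
                            variables = c("SBP", "DBP", "MEDS"),
                            levels = c("standard", "intensive"))
    pm <- participantMatrix(co)
    expect_equal(unname(pm[1, "RZ_MEDS"]), 6)
    expect_equal(unname(pm[1, "RZ_SBP"]), 250)
})

test_that("out-of-range raw values clamp with a warning, not an error", {
    vals <- matrix(c(300, 150, 140, 80, 79, 78, 1, 1, 1), 1)
    co <- Cohort(vals, arm = "standard", visits = c("RZ", "1M", "2M"),
                 variables = c("SBP", "DBP", "MEDS"),
                 levels = c("standard", "intensive"))
    expect_warning(m <- normalizeCohort(co), "clamped")
    expect_equal(unname(m[1, "RZ_SBP"]), 1)
})
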