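# Shared builders for small deterministic fixtures.

# A tiny complete cohort with a short schedule, values chosen by hand.
toyCohort <- function() {
    # 4 participants x (3 visits x 3 vars), variable-major columns
    vals <- rbind(
        c(150, 145, 130,  80, 78, 75, 1, 2, 2),
        c(135, 150, 150,  70, 72, 74, 0, 0, 1),
        c(118, 116, 115,  60, 61, 59, 2, 2, 2),
        c(125, 119, 117,  64, 66, 62, 1, 1, 1))
    Cohort(vals, arm = c("standard", "standard", "intensive", "intensive"),
           visits = c("RZ", "1M", "2M"), variables = c("SBP", "DBP", "MEDS"))
}

# Write a small full-schedule cohort CSV; returns the path.
writeToyCsv <- function(n = 3, path = tempfile(fileext = ".csv"),
                        armCase = FALSE) {
    schema <- cohortSchema()
    set.seed(42)
    co <- simulateTrial(trialSimParams(nParticipants = n, seed = 42))
    writeCohort(co, path)
    if (armCase) {
        df <- utils::read.csv(path, check.names = FALSE)
        df$arm <- toupper(df$arm)
        utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    path
}

# An untrained generator over the default trial schema (for shape and
# pooling tests that do not need a fitted model).
untrainedGenerator <- function(seed = 1) {
    dpsynth:::withSeed(seed, dpsynth:::initGenerator(
        100L, 8L, 32L, 36L,
        visits = cohortSchema()$visits,
        variables = cohortSchema()$variables,
        ranges = defaultRanges()))
}

# Small long-format event table with known per-patient measurement counts.
toyEvents <- function() {
    data.frame(
        patient_id = c(rep("A", 7), rep("B", 5), rep("C", 4)),
        variable = "hr",
        time = c(1:7, 1:5, 1:4),
        value = c(71:77, 81:85, 91:94),
        stringsAsFactors = FALSE)
}
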