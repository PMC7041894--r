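#' @describeIn Cohort-class number of participants.
#' @param x a \code{Cohort}.
#' @export
nParticipants <- function(x) ncol(x)

#' @describeIn Cohort-class participant ids, in record order.
#' @export
participantIds <- function(x) colnames(x)

#' @describeIn Cohort-class factor of per-participant arm labels.
#' @export
armLabels <- function(x) colData(x)$arm

#' @describeIn Cohort-class ordered visit labels.
#' @export
visitSchedule <- function(x) metadata(x)$visits

#' @describeIn Cohort-class ordered variable names.
#' @export
cohortVariables <- function(x) metadata(x)$variables

#' @describeIn Cohort-class participants-by-features numeric matrix in
#'   variable-major column order (all visits of the first variable first),
#'   the orientation used by training and evaluation code.
#' @export
participantMatrix <- function(x) t(assay(x, "values"))

#' @describeIn Cohort-class matrix of one variable across visits
#'   (participants x visits).
#' @param variable variable name.
#' @export
variableMatrix <- function(x, variable) {
    keep <- rowData(x)$variable == variable
    if (!any(keep)) stop(sprintf("unknown variable '%s'", variable))
    m <- t(assay(x, "values")[keep, , drop = FALSE])
    colnames(m) <- rowData(x)$visit[keep]
    m
}

setMethod("show", "Cohort", function(object) {
    cat(sprintf("Cohort with %d participants\n", ncol(object)))
    cat(sprintf("  visits(%d): %s\n", length(visitSchedule(object)),
                paste(visitSchedule(object), collapse = " ")))
    cat(sprintf("  variables: %s\n",
                paste(cohortVariables(object), collapse = ", ")))
    tab <- table(armLabels(object))
    cat(sprintf("  arms: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    nmiss <- sum(is.na(assay(object, "values")))
    if (nmiss > 0) cat(sprintf("  missing entries: %d\n", nmiss))
})

#' Default cohort schema
#'
#' Column-naming convention for cohort CSV files: an id column, an arm
#' column, and one \code{<visit>_<variable>} column per measurement
#' (e.g. \code{RZ_SBP}). The default schedule is the 12 trial visits
#' RZ, 1M, 2M, 3M, 6M, 9M, 12M, 15M, 18M, 21M, 24M, 27M, with variables
#' SBP, DBP (mmHg) and MEDS (medication count). Empty cells and \code{NA}
#' are missing-value sentinels.
#'
#' @param visits ordered visit labels.
#' @param variables ordered variable names.
#' @param idColumn,armColumn CSV column names.
#' @param armLevels arm level order.
#' @return a list understood by [readCohort()] and [writeCohort()].
#' @export
cohortSchema <- function(visits = c("RZ", "1M", "2M", "3M", "6M", "9M",
                                    "12M", "15M", "18M", "21M", "24M", "27M"),
                         variables = c("SBP", "DBP", "MEDS"),
                         idColumn = "id", armColumn = "arm",
                         armLevels = c("standard", "intensive")) {
    list(visits = visits, variables = variables,
         idColumn = idColumn, armColumn = armColumn, armLevels = armLevels)
}

#' Read a cohort from CSV
#'
#' One row per participant; columns named per the schema
#' (\code{<visit>_<variable>}). Arm labels are matched case-insensitively
#' against the schema's levels. Empty cells and \code{"NA"} parse to
#' missing; any other non-numeric cell is an error naming the offending
#' row and column.
#'
#' @param path CSV file.
#' @param schema see [cohortSchema()].
#' @return a \linkS4class{Cohort}.
#' @export
readCohort <- function(path, schema = cohortSchema()) {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
    wanted <- paste(rep(schema$visits, times = length(schema$variables)),
                    rep(schema$variables, each = length(schema$visits)),
                    sep = "_")
    missing_cols <- setdiff(c(schema$idColumn, schema$armColumn, wanted),
                            colnames(df))
    if (length(missing_cols)) {
        stop(sprintf("cohort file is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")))
    }
    vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(wanted),
                   dimnames = list(NULL, wanted))
    for (j in seq_along(wanted)) {
        cell <- df[[wanted[j]]]
        num <- suppressWarnings(as.numeric(cell))
        bad <- which(!is.na(cell) & is.na(num))
        if (length(bad)) {
            stop(sprintf("non-numeric value '%s' at row %d, column %s",
                         cell[bad[1]], bad[1], wanted[j]))
        }
        vals[, j] <- num
    }
    arm_raw <- tolower(trimws(df[[schema$armColumn]]))
    lv <- schema$armLevels
    idx <- match(arm_raw, tolower(lv))
    if (anyNA(idx)) {
        stop(sprintf("unrecognised arm label '%s'",
                     df[[schema$armColumn]][which(is.na(idx))[1]]))
    }
    Cohort(vals, arm = lv[idx], visits = schema$visits,
           variables = schema$variables, ids = df[[schema$idColumn]],
           levels = lv)
}

#' Write a cohort to CSV in the same dialect [readCohort()] reads
#'
#' @param x a \linkS4class{Cohort}.
#' @param path output file.
#' @param schema naming convention; visits/variables are taken from the
#'   cohort itself.
#' @export
writeCohort <- function(x, path, schema = cohortSchema()) {
    m <- participantMatrix(x)
    df <- data.frame(id = participantIds(x),
                     arm = as.character(armLabels(x)),
                     m, check.names = FALSE)
    names(df)[1:2] <- c(schema$idColumn, schema$armColumn)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' Keep only participants with complete measurements
#'
#' Retains records that have a non-missing value for every variable at each
#' of the first \code{requiredVisits} visits, preserving record order.
#' Mirrors the trial inclusion rule of keeping participants with blood
#' pressure measured at each of the first 12 visits.
#'
#' @param x a \linkS4class{Cohort}, possibly containing \code{NA}s.
#' @param requiredVisits number of leading visits that must be complete
#'   (default: the whole schedule).
#' @return the filtered \linkS4class{Cohort}. Idempotent.
#' @export
filterComplete <- function(x, requiredVisits = length(visitSchedule(x))) {
    visits <- visitSchedule(x)
    if (requiredVisits > length(visits)) {
        stop(sprintf("requiredVisits (%d) exceeds schedule length (%d)",
                     requiredVisits, length(visits)))
    }
    need <- rowData(x)$visit %in% visits[seq_len(requiredVisits)]
    ok <- colSums(is.na(assay(x, "values")[need, , drop = FALSE])) == 0L
    x[, ok]
}

#' Split a cohort into training and held-out test sets
#'
#' Seeded uniform shuffle followed by a deterministic cut: a disjoint,
#' exhaustive partition reproducible for a fixed seed.
#'
#' @param x a \linkS4class{Cohort}.
#' @param nTrain number of training participants; must be < the cohort size.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
splitTrainTest <- function(x, nTrain, seed = 1L) {
    n <- nParticipants(x)
    if (nTrain >= n) stop("nTrain must be smaller than the cohort size")
    if (nTrain < 0) stop("nTrain must be non-negative")
    perm <- withSeed(seed, sample.int(n))
    idx <- perm[seq_len(nTrain)]
    list(train = x[, sort(idx)], test = x[, sort(setdiff(seq_len(n), idx))])
}

#' Fixed physiologic normalisation ranges
#'
#' Per-variable (min, max) used to map measurements affinely into [-1, 1]
#' for network training. The ranges are a-priori physiologic constants --
#' SBP (60, 250) mmHg, DBP (30, 150) mmHg, medications (0, 10) -- rather
#' than data-derived extrema, so computing them consumes no privacy budget.
#'
#' @param variables variable names to cover.
#' @return named list of length-2 numeric vectors.
#' @export
defaultRanges <- function(variables = c("SBP", "DBP", "MEDS")) {
    known <- list(SBP = c(60, 250), DBP = c(30, 150), MEDS = c(0, 10))
    missing <- setdiff(variables, names(known))
    if (length(missing)) {
        stop(sprintf("no default range for variable(s): %s; supply 'ranges'",
                     paste(missing, collapse = ", ")))
    }
    known[variables]
}

#' Normalise a cohort into [-1, 1]
#'
#' Applies, per variable, the affine map x -> (x - mid) / halfwidth defined
#' by fixed a-priori ranges. Values outside their range are clamped with a
#' warning (never an error). The inverse is [denormalizeMatrix()].
#'
#' @param x a \linkS4class{Cohort}.
#' @param ranges named list of per-variable (min, max); see
#'   [defaultRanges()].
#' @return participants-by-features matrix in [-1, 1], variable-major
#'   column order.
#' @export
normalizeCohort <- function(x, ranges = defaultRanges(cohortVariables(x))) {
    m <- participantMatrix(x)
    vars <- rowData(x)$variable
    nclamp <- 0L
    for (v in unique(vars)) {
        r <- ranges[[v]]
        if (is.null(r)) stop(sprintf("no range supplied for variable '%s'", v))
        cols <- which(vars == v)
        block <- m[, cols, drop = FALSE]
        out <- !is.na(block) & (block < r[1] | block > r[2])
        nclamp <- nclamp + sum(out)
        block[block < r[1]] <- r[1]
        block[block > r[2]] <- r[2]
        mid <- mean(r); half <- diff(r) / 2
        m[, cols] <- (block - mid) / half
    }
    if (nclamp > 0) {
        warning(sprintf("%d value(s) outside their declared range were clamped",
                        nclamp))
    }
    m
}

#' Invert [normalizeCohort()]
#'
#' Maps a normalised matrix back to measurement units, clamping to each
#' variable's range and rounding count variables to non-negative integers.
#'
#' @param m participants-by-features matrix in [-1, 1] (variable-major).
#' @param arm per-row arm labels.
#' @param visits,variables schedule and variable order of the matrix.
#' @param ranges named list of per-variable (min, max).
#' @param countVariables variables rounded to integer counts.
#' @param ids optional participant ids.
#' @param levels optional arm level order.
#' @return a \linkS4class{Cohort}.
#' @export
denormalizeMatrix <- function(m, arm,
                              visits = cohortSchema()$visits,
                              variables = cohortSchema()$variables,
                              ranges = defaultRanges(variables),
                              countVariables = "MEDS",
                              ids = NULL, levels = NULL) {
    m <- as.matrix(m)
    nv <- length(visits)
    vars <- rep(variables, each = nv)
    for (v in variables) {
        r <- ranges[[v]]
        cols <- which(vars == v)
        mid <- mean(r); half <- diff(r) / 2
        block <- m[, cols, drop = FALSE] * half + mid
        block[block < r[1]] <- r[1]
        block[block > r[2]] <- r[2]
        if (v %in% countVariables) block <- pmax(round(block), 0)
        m[, cols] <- block
    }
    Cohort(m, arm = arm, visits = visits, variables = variables,
           ids = ids, levels = levels)
}

# rbind-like combination used by pooled generation.
bindCohorts <- function(cohorts) {
    stopifnot(length(cohorts) >= 1L)
    visits <- visitSchedule(cohorts[[1]])
    variables <- cohortVariables(cohorts[[1]])
    lv <- levels(armLabels(cohorts[[1]]))
    vals <- do.call(rbind, lapply(cohorts, participantMatrix))
    arm <- unlist(lapply(cohorts, function(co) as.character(armLabels(co))))
    Cohort(vals, arm = arm, visits = visits, variables = variables,
           levels = lv)
}
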