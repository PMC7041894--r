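#' ICD-9 codes defining heart failure
#'
#' The Veterans Affairs Chronic Heart Failure QUERI guideline code list used
#' to label heart-failure cases in critical-care EHR data. Matching is exact
#' on the normalised code string (whitespace stripped); "428" matches the
#' literal code "428" only, never "428.x" -- the list already enumerates the
#' decimal children it intends. Users wanting prefix semantics can expand
#' the list themselves.
#'
#' @return character vector of ICD-9 codes.
#' @export
heartFailureCodes <- function() {
    c("402.01", "402.11", "402.91", "404.01", "404.03", "404.11", "404.13",
      "404.91", "404.93", "428", "281.1", "428.20", "428.21", "428.22",
      "428.23", "428.30", "428.31", "428.32", "428.33", "428.40", "428.41",
      "428.42", "428.43", "428.9")
}

#' The nine vital-sign variables of the EHR prediction task
#' @return character vector of variable names.
#' @export
vitalsVariables <- function() {
    c("map", "art_sbp", "art_dbp", "bpm", "resp_rate", "spo2",
      "ni_map", "ni_sbp", "ni_dbp")
}

checkEventTable <- function(events) {
    need <- c("patient_id", "variable", "time", "value")
    if (!all(need %in% colnames(events))) {
        stop(sprintf("event table must have columns: %s",
                     paste(need, collapse = ", ")))
    }
    events
}

#' Label patients by diagnosis-code membership
#'
#' @param diagnoses data.frame with columns \code{patient_id} and
#'   \code{code} (ICD-9 strings).
#' @param patientIds patients to label (defines output order).
#' @param codes code list; default [heartFailureCodes()]. Exact match after
#'   stripping whitespace.
#' @return named integer vector of 0/1 labels, 1 iff the patient carries at
#'   least one listed code.
#' @export
labelHeartFailure <- function(diagnoses, patientIds,
                              codes = heartFailureCodes()) {
    codes <- trimws(codes)
    hit <- unique(diagnoses$patient_id[trimws(diagnoses$code) %in% codes])
    stats::setNames(as.integer(patientIds %in% hit), patientIds)
}

#' First k measurements per patient and variable
#'
#' Complete-case extraction for the EHR task: patients lacking at least
#' \code{k} measurements of any listed variable are dropped; for the rest,
#' the \code{k} earliest values of each variable (time order) are kept and
#' concatenated in fixed variable order.
#'
#' @param events long-format data.frame (patient_id, variable, time, value).
#' @param variables ordered variable names to extract.
#' @param k measurements kept per variable.
#' @return numeric matrix, one row per retained patient in id order
#'   (rownames = ids),
#'   \code{k * length(variables)} columns in variable-major order, with a
#'   \code{"patients"} attribute listing retained ids.
#' @export
firstKMeasurements <- function(events, variables = vitalsVariables(), k = 5L) {
    checkEventTable(events)
    unknown <- setdiff(variables, unique(events$variable))
    if (length(unknown)) {
        stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")))
    }
    events <- events[events$variable %in% variables, , drop = FALSE]
    events <- events[order(events$patient_id, events$variable, events$time), ,
                     drop = FALSE]
    grp <- interaction(events$patient_id, events$variable, drop = TRUE)
    within <- stats::ave(seq_along(grp), grp, FUN = seq_along)
    counts <- table(events$patient_id, events$variable)
    ids <- rownames(counts)
    complete <- ids[apply(counts[, variables, drop = FALSE] >= k, 1, all)]
    keep <- within <= k & events$patient_id %in% complete
    ev <- events[keep, , drop = FALSE]
    out <- matrix(NA_real_, nrow = length(complete),
                  ncol = k * length(variables),
                  dimnames = list(complete,
                                  paste(rep(variables, each = k),
                                        rep(seq_len(k), length(variables)),
                                        sep = "_t")))
    rowIdx <- match(ev$patient_id, complete)
    colIdx <- (match(ev$variable, variables) - 1L) * k + within[keep]
    out[cbind(rowIdx, colIdx)] <- ev$value
    out
}

#' Assemble an EHR feature matrix into a Cohort
#'
#' Convenience wrapper giving [firstKMeasurements()] output the same
#' container as trial data, with the case/control label in the arm slot so
#' the GAN and evaluation machinery apply unchanged.
#'
#' @param features matrix from [firstKMeasurements()].
#' @param labels named 0/1 vector from [labelHeartFailure()].
#' @param variables,k as used for extraction.
#' @return a \linkS4class{Cohort} with arm levels \code{control}/\code{case}
#'   and visit labels \code{t1..tk}.
#' @export
ehrCohort <- function(features, labels, variables = vitalsVariables(), k = 5L) {
    ids <- rownames(features)
    arm <- ifelse(labels[ids] == 1L, "case", "control")
    Cohort(features, arm = arm, visits = paste0("t", seq_len(k)),
           variables = variables, ids = ids, levels = c("control", "case"))
}
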