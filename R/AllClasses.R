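#' Canonical abnormality class order
#'
#' The six ECG abnormality classes handled throughout the package, in the
#' canonical order used by every label vector, label matrix, CSV sidecar and
#' network output: first-degree AV block (1dAVb), right bundle branch block
#' (RBBB), left bundle branch block (LBBB), sinus bradycardia (SB), atrial
#' fibrillation (AF) and sinus tachycardia (ST).
#'
#' @return Character vector of length 6.
#' @export
ecgClasses <- function() c("1dAVb", "RBBB", "LBBB", "SB", "AF", "ST")

#' Standard 12-lead names
#' @return Character vector of length 12 (I, II, III, aVR, aVL, aVF, V1-V6).
#' @export
ecgLeads <- function() c("I", "II", "III", "aVR", "aVL", "aVF",
                         "V1", "V2", "V3", "V4", "V5", "V6")

#' ECGRecord: a single 12-lead ECG exam
#'
#' Holds the lead-by-sample signal matrix of one short-duration standard
#' 12-lead ECG together with its sampling rate and exam/patient metadata.
#'
#' @slot signal numeric matrix, samples x 12 leads, in millivolt.
#' @slot fs sampling rate in Hz.
#' @slot examId,patientId identifiers.
#' @slot age age in years (NA allowed).
#' @slot sex "M", "F" or NA.
#' @slot date acquisition date as "YYYY-MM-DD" character (NA allowed); used
#'   only by chronological dataset splits.
#'
#' @aliases ECGRecord-class
#' @export
setClass("ECGRecord",
  representation(signal = "matrix", fs = "numeric", examId = "character",
                 patientId = "character", age = "numeric", sex = "character",
                 date = "character"),
  prototype(age = NA_real_, sex = NA_character_, date = NA_character_))

setValidity("ECGRecord", function(object) {
  msg <- character()
  if (ncol(object@signal) != 12L)
    msg <- c(msg, sprintf("signal must have 12 lead columns, got %d",
                          ncol(object@signal)))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!all(is.finite(object@signal)))
    msg <- c(msg, "signal contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecord
#'
#' @param signal samples x 12 numeric matrix (mV).
#' @param fs sampling rate (Hz).
#' @param examId,patientId identifiers (defaults generated).
#' @param age,sex,date optional metadata.
#' @return An [ECGRecord-class] object.
#' @export
ECGRecord <- function(signal, fs, examId = "exam1", patientId = examId,
                      age = NA_real_, sex = NA_character_,
                      date = NA_character_) {
  signal <- as.matrix(signal)
  colnames(signal) <- ecgLeads()
  methods::new("ECGRecord", signal = signal, fs = as.numeric(fs),
               examId = as.character(examId),
               patientId = as.character(patientId), age = as.numeric(age),
               sex = as.character(sex), date = as.character(date))
}

#' @describeIn ECGRecord signal matrix accessor (samples x 12, mV)
#' @param object,x an ECGRecord
#' @export
setGeneric("ecgSignal", function(object) standardGeneric("ecgSignal"))
#' @export
setMethod("ecgSignal", "ECGRecord", function(object) object@signal)

#' @describeIn ECGRecord sampling rate accessor (Hz)
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @export
setMethod("samplingRate", "ECGRecord", function(object) object@fs)

#' @describeIn ECGRecord exam identifier accessor
#' @export
setGeneric("examId", function(object) standardGeneric("examId"))
#' @export
setMethod("examId", "ECGRecord", function(object) object@examId)

#' @describeIn ECGRecord record duration in seconds
#' @export
setGeneric("recordDuration", function(object) standardGeneric("recordDuration"))
#' @export
setMethod("recordDuration", "ECGRecord",
          function(object) nrow(object@signal) / object@fs)

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord %s: %d samples x 12 leads @ %g Hz (%.2f s)\n",
              object@examId, nrow(object@signal), object@fs,
              recordDuration(object)))
})

#' ECGDataset: a collection of ECG records with labels and metadata
#'
#' @slot records list of [ECGRecord-class] objects.
#' @slot labels data.frame with one row per record: exam_id, the six class
#'   columns in canonical order (logical), age, sex, patient_id, date.
#' @slot measurements optional data.frame of generator ground-truth
#'   measurements (heart_rate, pr_interval, qrs_duration, sdnn, n_beats),
#'   one row per record; zero rows when unknown.
#'
#' @aliases ECGDataset-class
#' @export
setClass("ECGDataset",
  representation(records = "list", labels = "data.frame",
                 measurements = "data.frame"),
  prototype(measurements = data.frame()))

setValidity("ECGDataset", function(object) {
  msg <- character()
  if (!all(vapply(object@records, methods::is, logical(1), "ECGRecord")))
    msg <- c(msg, "records must all be ECGRecord objects")
  if (nrow(object@labels) != length(object@records))
    msg <- c(msg, "labels must have one row per record")
  if (!all(ecgClasses() %in% names(object@labels)))
    msg <- c(msg, "labels must contain the six canonical class columns")
  if (nrow(object@measurements) &&
      nrow(object@measurements) != length(object@records))
    msg <- c(msg, "measurements must be empty or one row per record")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGDataset
#' @param records list of ECGRecord.
#' @param labels data.frame sidecar (see [ECGDataset-class]).
#' @param measurements optional ground-truth measurement data.frame.
#' @return An [ECGDataset-class] object.
#' @export
ECGDataset <- function(records, labels, measurements = data.frame()) {
  methods::new("ECGDataset", records = records, labels = labels,
               measurements = measurements)
}

#' @describeIn ECGDataset number of records
#' @param object an ECGDataset
#' @export
setGeneric("recordCount", function(object) standardGeneric("recordCount"))
#' @export
setMethod("recordCount", "ECGDataset", function(object) length(object@records))

#' @describeIn ECGDataset list of records
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @export
setMethod("records", "ECGDataset", function(object) object@records)

#' @describeIn ECGDataset label sidecar data.frame
#' @export
setGeneric("labelSidecar", function(object) standardGeneric("labelSidecar"))
#' @export
setMethod("labelSidecar", "ECGDataset", function(object) object@labels)

#' @describeIn ECGDataset n x 6 logical label matrix in canonical class order
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @export
setMethod("labelMatrix", "ECGDataset", function(object) {
  m <- as.matrix(object@labels[, ecgClasses(), drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- object@labels$exam_id
  m
})

#' @describeIn ECGDataset generator ground-truth measurements (may be empty)
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @export
setMethod("groundTruth", "ECGDataset", function(object) object@measurements)

setMethod("show", "ECGDataset", function(object) {
  n <- recordCount(object)
  cat(sprintf("ECGDataset: %d records\n", n))
  if (n) {
    prev <- colMeans(as.matrix(object@labels[, ecgClasses()]))
    cat("  prevalence:",
        paste(sprintf("%s %.1f%%", ecgClasses(), 100 * prev), collapse = ", "),
        "\n")
  }
})

#' @describeIn ECGDataset subset a dataset by record index
#' @param i integer/logical index
#' @param j,...,drop ignored
#' @export
setMethod("[", "ECGDataset", function(x, i, j, ..., drop = FALSE) {
  meas <- if (nrow(x@measurements)) x@measurements[i, , drop = FALSE]
          else x@measurements
  ECGDataset(x@records[i], x@labels[i, , drop = FALSE], meas)
})

# -- light S3 record types ---------------------------------------------------

#' A set of interval/rate measurements for one ECG record
#'
#' @param heart_rate beats per minute (60 / mean RR).
#' @param pr_interval PR interval in ms (P onset to QRS onset); NA if no P.
#' @param qrs_duration QRS duration in ms.
#' @param sdnn standard deviation of NN intervals, in ms by default.
#' @param n_beats number of detected (or generated) beats.
#' @param p_present logical: was a P wave present/detected.
#' @return object of class "MeasurementSet" (named list).
#' @export
measurementSet <- function(heart_rate = NA_real_, pr_interval = NA_real_,
                           qrs_duration = NA_real_, sdnn = NA_real_,
                           n_beats = NA_integer_, p_present = NA) {
  stopifnot(is.na(heart_rate) || heart_rate >= 0,
            is.na(pr_interval) || pr_interval >= 0,
            is.na(qrs_duration) || qrs_duration >= 0,
            is.na(sdnn) || sdnn >= 0)
  structure(list(heart_rate = heart_rate, pr_interval = pr_interval,
                 qrs_duration = qrs_duration, sdnn = sdnn,
                 n_beats = n_beats, p_present = p_present),
            class = "MeasurementSet")
}

#' @export
print.MeasurementSet <- function(x, ...) {
  cat(sprintf(
    "MeasurementSet: HR %.1f bpm, PR %s ms, QRS %s ms, SDNN %s, beats %s\n",
    x$heart_rate, format(x$pr_interval), format(x$qrs_duration),
    format(x$sdnn), format(x$n_beats)))
  invisible(x)
}

#' Build a named logical label vector in canonical class order
#'
#' @param ... class names to set TRUE (e.g. `labelVector("SB")`), or a single
#'   named logical/numeric vector.
#' @return named logical vector of length 6.
#' @export
labelVector <- function(...) {
  v <- stats::setNames(rep(FALSE, 6L), ecgClasses())
  args <- list(...)
  if (length(args) == 1L && !is.null(names(args[[1]]))) {
    x <- args[[1]]
    bad <- setdiff(names(x), ecgClasses())
    if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = ", "))
    v[names(x)] <- as.logical(x)
  } else if (length(args)) {
    cls <- unlist(args)
    bad <- setdiff(cls, ecgClasses())
    if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = ", "))
    v[cls] <- TRUE
  }
  v
}
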