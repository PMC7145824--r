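# Dataset container I/O: one HDF5 tensor (N x samples x 12, dataset
# "tracings") plus a CSV label/metadata sidecar with header
# exam_id,1dAVb,RBBB,LBBB,SB,AF,ST,age,sex,patient_id,date.

.sidecarCols <- function() c("exam_id", ecgClasses(), "age", "sex",
                             "patient_id", "date")

.defaultLabelsPath <- function(path) {
  paste0(sub("\\.(h5|hdf5)$", "", path), "_labels.csv")
}

#' Write an ECG dataset container
#'
#' Writes the HDF5 tracing tensor and the CSV label/metadata sidecar. Records
#' are preprocessed to a common shape (400 Hz, 4096 samples per lead) so the
#' container holds a fixed `n x 4096 x 12` tensor, matching the layout of the
#' released study test set.
#'
#' @param ds an [ECGDataset-class].
#' @param path HDF5 file path.
#' @param labelsPath CSV sidecar path (default: `path` with `_labels.csv`).
#' @param target_fs,target_len container sampling rate and samples per lead.
#' @return invisibly, the two paths written.
#' @export
writeDataset <- function(ds, path, labelsPath = NULL,
                         target_fs = 400, target_len = 4096) {
  stopifnot(methods::is(ds, "ECGDataset"))
  if (is.null(labelsPath)) labelsPath <- .defaultLabelsPath(path)
  pp <- preprocessDataset(ds, target_fs, target_len)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(pp$x, path, "tracings")
  rhdf5::h5closeAll()
  meta <- labelSidecar(ds)
  out <- data.frame(exam_id = meta$exam_id)
  for (cl in ecgClasses()) out[[cl]] <- as.integer(meta[[cl]])
  out$age <- meta$age; out$sex <- meta$sex
  out$patient_id <- meta$patient_id; out$date <- meta$date
  utils::write.csv(out, labelsPath, row.names = FALSE, quote = FALSE)
  invisible(c(tracings = path, labels = labelsPath))
}

#' Read an ECG dataset container
#'
#' Reads the HDF5 tracing tensor (dataset "tracings", shape N x samples x 12)
#' and, when present, the CSV label sidecar whose row i pairs with tracing i.
#' Files written with C-order libraries (tracings stored as 12 x samples x N
#' from R's column-major view) are transposed automatically.
#'
#' @param path HDF5 file path.
#' @param labelsPath CSV sidecar path; `NULL` tries the default location and
#'   proceeds without labels when absent.
#' @param fs sampling rate of the stored tracings (default 400 Hz).
#' @param name HDF5 dataset name (default "tracings").
#' @return an [ECGDataset-class].
#' @export
readDataset <- function(path, labelsPath = NULL, fs = 400,
                        name = "tracings") {
  if (!file.exists(path)) stop("container not found: ", path)
  x <- rhdf5::h5read(path, name)
  rhdf5::h5closeAll()
  d <- dim(x)
  if (length(d) != 3L) stop("tracing tensor must be 3-dimensional")
  if (d[3] != 12L) {
    if (d[1] == 12L) x <- aperm(x, c(3, 2, 1))
    else stop(sprintf("tracing tensor must have 12 leads, got dims %s",
                      paste(d, collapse = " x ")))
  }
  n <- dim(x)[1]
  labels <- NULL
  if (is.null(labelsPath)) {
    cand <- .defaultLabelsPath(path)
    if (file.exists(cand)) labelsPath <- cand
  }
  if (!is.null(labelsPath)) {
    labels <- utils::read.csv(labelsPath, check.names = FALSE,
                              colClasses = c(date = "character"))
    if (nrow(labels) != n)
      stop(sprintf("label sidecar has %d rows but container has %d tracings",
                   nrow(labels), n))
    missing <- setdiff(c("exam_id", ecgClasses()), names(labels))
    if (length(missing))
      stop("label sidecar lacks column(s): ", paste(missing, collapse = ", "))
    for (cl in ecgClasses()) labels[[cl]] <- as.logical(labels[[cl]])
    for (col in c("age", "sex", "patient_id", "date"))
      if (is.null(labels[[col]])) labels[[col]] <- NA
    if (all(is.na(labels$patient_id))) labels$patient_id <- labels$exam_id
  } else {
    labels <- data.frame(exam_id = sprintf("exam_%06d", seq_len(n)))
    for (cl in ecgClasses()) labels[[cl]] <- NA
    labels$age <- NA_real_; labels$sex <- NA_character_
    labels$patient_id <- labels$exam_id; labels$date <- NA_character_
  }
  recs <- lapply(seq_len(n), function(i) {
    ECGRecord(x[i, , ], fs, examId = as.character(labels$exam_id[i]),
              patientId = as.character(labels$patient_id[i]),
              age = as.numeric(labels$age[i]),
              sex = as.character(labels$sex[i]),
              date = as.character(labels$date[i]))
  })
  ECGDataset(recs, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
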