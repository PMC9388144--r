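#' Read and write recordings
#'
#' The on-disk interchange format is deliberately plain: a delimited-text
#' signal file with one row per signal channel (wavelength-major for raw
#' fNIRS intensities) and a JSON sidecar holding `fs`, `channel_names`,
#' `modality`, `wavelengths` and the 0-based event list. Values are written
#' with full round-trip precision, so `read_recording()` inverts
#' `write_recording()` bit-exactly.
#'
#' @param signal_path path to the CSV signal file (one channel per row,
#'   no header).
#' @param sidecar_path path to the JSON sidecar.
#' @return `read_recording()` returns a [recording()]; `write_recording()`
#'   returns its input invisibly.
#' @export
read_recording <- function(signal_path, sidecar_path) {
  if (!file.exists(signal_path)) abort(paste0("no such signal file: ", signal_path))
  if (!file.exists(sidecar_path)) abort(paste0("no such sidecar: ", sidecar_path))
  meta <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) abort("sidecar is missing `fs`")
  if (is.null(meta$channel_names)) abort("sidecar is missing `channel_names`")
  if (is.null(meta$modality)) abort("sidecar is missing `modality`")
  sig <- as.matrix(utils::read.table(signal_path, sep = ",", header = FALSE,
                                     colClasses = "numeric"))
  dimnames(sig) <- NULL
  expected <- length(meta$channel_names) *
    (if (identical(meta$modality, "nirs_intensity")) 2L else 1L)
  if (nrow(sig) != expected) {
    abort(sprintf("signal has %d rows but sidecar names %d channel rows",
                  nrow(sig), expected))
  }
  events <- meta$events
  if (is.null(events) || length(events) == 0) {
    events <- tibble::tibble(onset = integer(), label = character())
  } else {
    events <- tibble::tibble(onset = as.integer(events$onset),
                             label = as.character(events$label))
  }
  recording(sig, fs = meta$fs, channel_names = meta$channel_names,
            modality = meta$modality, events = events,
            wavelengths = meta$wavelengths)
}

#' @rdname read_recording
#' @param rec a [recording()].
#' @export
write_recording <- function(rec, signal_path, sidecar_path) {
  stopifnot(inherits(rec, "bci_recording"))
  lines <- apply(rec$signal, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  })
  tryCatch(
    writeLines(lines, signal_path),
    error = function(e) abort(paste0("cannot write signal file: ", conditionMessage(e)))
  )
  meta <- list(
    fs = rec$fs,
    channel_names = rec$channel_names,
    modality = rec$modality,
    layout = if (rec$modality == "nirs_intensity") "wavelength-major" else "channel-major",
    events = if (nrow(rec$events) == 0) list() else
      lapply(seq_len(nrow(rec$events)), function(i) {
        list(onset = rec$events$onset[i], label = rec$events$label[i])
      })
  )
  if (!is.null(rec$wavelengths)) meta$wavelengths <- rec$wavelengths
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}

#' Read and write feature matrices
#'
#' Feature matrices are exchanged as CSV with a header of unique feature
#' names and a final integer `label` column. Values are written with 17
#' significant digits so round-trips are lossless.
#'
#' @param path CSV file path.
#' @return `read_features()` returns a [feature_matrix()] tibble.
#' @export
read_features <- function(path, modality = NA_character_, domain = NA_character_) {
  if (!file.exists(path)) abort(paste0("no such feature file: ", path))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", header)
  if (anyDuplicated(header)) abort("duplicate feature names in header")
  if (utils::tail(header, 1) != "label") abort("final column must be `label`")
  if (length(header) < 2L) abort("feature file has no feature columns")
  # base strtod parsing keeps the 17-digit decimal round-trip bit-exact
  tbl <- utils::read.csv(path, check.names = FALSE)
  feature_matrix(as.matrix(tbl[, -ncol(tbl), drop = FALSE]),
                 header[-length(header)], tbl$label,
                 modality = modality, domain = domain)
}

#' @rdname read_features
#' @param fm a `bci_features` tibble.
#' @param modality,domain tags to attach on read (not stored in the CSV).
#' @export
write_features <- function(fm, path) {
  if (ncol(fm) < 2L) abort("refusing to write a feature matrix with no features")
  vals <- feature_values(fm)
  header <- paste(c(feature_names(fm), "label"), collapse = ",")
  rows <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(sprintf("%.17g", vals[i, ]), sprintf("%d", fm$label[i])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(fm)
}
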