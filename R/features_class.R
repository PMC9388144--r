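#' Feature matrix
#'
#' Feature matrices are plain tibbles: one row per classification sample
#' (1-s subtask), one numeric column per named feature, plus an integer
#' `label` column. The modality and feature-domain tags travel as
#' attributes so pipelines can check pairing without extra arguments.
#'
#' @param values numeric matrix, samples by features.
#' @param feature_names unique character vector of column names.
#' @param labels integer class label (0/1) per row.
#' @param modality modality tag (`"eeg"`, `"nirs_hb"`, ...).
#' @param domain feature domain tag (`"time"`, `"freq"`, `"multi"`).
#' @return tibble of class `bci_features` with a final `label` column.
#' @export
feature_matrix <- function(values, feature_names, labels, modality = NA_character_,
                           domain = NA_character_) {
  values <- as.matrix(values)
  if (anyDuplicated(feature_names)) abort("feature names must be unique")
  if (ncol(values) != length(feature_names)) {
    abort("`feature_names` must have one entry per column")
  }
  if (nrow(values) != length(labels)) abort("one label per row required")
  if ("label" %in% feature_names) abort("`label` is reserved for the class column")
  out <- tibble::as_tibble(as.data.frame(values, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- feature_names
  out$label <- as.integer(labels)
  new_bci_features(out, modality, domain)
}

new_bci_features <- function(tbl, modality, domain) {
  structure(
    tbl,
    class = c("bci_features", class(tibble::tibble())),
    modality = modality,
    domain = domain
  )
}

#' @export
print.bci_features <- function(x, ...) {
  cat(sprintf(
    "<bci_features> modality=%s domain=%s: %d sample(s) x %d feature(s)\n",
    attr(x, "modality"), attr(x, "domain"), nrow(x), ncol(x) - 1L
  ))
  NextMethod()
}

#' @rdname feature_matrix
#' @param fm a `bci_features` tibble.
#' @export
feature_values <- function(fm) {
  as.matrix(fm[setdiff(names(fm), "label")])
}

#' @rdname feature_matrix
#' @export
feature_names <- function(fm) setdiff(names(fm), "label")

#' @rdname feature_matrix
#' @export
feature_labels <- function(fm) as.integer(fm$label)

feature_modality <- function(fm) attr(fm, "modality")

assert_no_nonfinite <- function(fm, context) {
  if (!all(is.finite(feature_values(fm)))) {
    abort(paste0("non-finite feature values after ", context))
  }
  invisible(fm)
}

#' Column-wise union of two feature domains
#'
#' Concatenates a time-domain and a frequency-domain feature matrix of the
#' same samples into one multi-domain matrix. Rows, labels and modality
#' must agree; feature names must stay unique.
#'
#' @param time_fm,freq_fm `bci_features` tibbles over identical samples.
#' @return combined `bci_features` tibble, domain `"multi"`.
#' @export
combine_domains <- function(time_fm, freq_fm) {
  if (ncol(freq_fm) == 1L && nrow(freq_fm) == 0L) return(time_fm)
  if (nrow(time_fm) != nrow(freq_fm)) abort("row counts differ between domains")
  if (!identical(feature_labels(time_fm), feature_labels(freq_fm))) {
    abort("labels differ between domains")
  }
  m1 <- attr(time_fm, "modality"); m2 <- attr(freq_fm, "modality")
  if (!is.na(m1) && !is.na(m2) && !identical(m1, m2)) {
    abort("modalities differ between domains")
  }
  nm <- c(feature_names(time_fm), feature_names(freq_fm))
  if (anyDuplicated(nm)) abort("combined feature names must be unique")
  feature_matrix(
    cbind(feature_values(time_fm), feature_values(freq_fm)),
    nm, feature_labels(time_fm),
    modality = if (!is.na(m1)) m1 else m2, domain = "multi"
  )
}
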