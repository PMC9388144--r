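#' Continuous multichannel recording
#'
#' The basic container for a continuous signal stream: a channels-by-samples
#' numeric matrix plus sampling rate, channel names, modality tag and event
#' markers. Three modalities are distinguished:
#' \describe{
#'   \item{`eeg`}{scalp potentials, microvolts.}
#'   \item{`nirs_intensity`}{raw dual-wavelength optical intensities
#'     (arbitrary detector units). The matrix holds `2 * n_channels` rows in
#'     wavelength-major order: all first-wavelength channels, then all
#'     second-wavelength channels. `wavelengths` must name the two
#'     wavelengths in nm.}
#'   \item{`nirs_hb`}{chromophore concentration changes (micromolar), HbO
#'     block of rows followed by the Hb block.}
#' }
#' Event onsets are 0-based sample indices; time windows throughout the
#' package are half-open `[t0, t1)` seconds.
#'
#' @param signal numeric matrix, channels (rows) by samples (columns).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector naming the physical channels (for
#'   `nirs_intensity` the per-wavelength rows share these names).
#' @param modality one of `"eeg"`, `"nirs_intensity"`, `"nirs_hb"`.
#' @param events tibble/data frame with integer column `onset` (0-based
#'   sample index) and character column `label`.
#' @param wavelengths numeric length-2 vector of wavelengths in nm
#'   (`nirs_intensity` only).
#' @return An object of class `bci_recording`.
#' @export
recording <- function(signal, fs, channel_names, modality,
                      events = NULL, wavelengths = NULL) {
  signal <- as.matrix(signal)
  if (!is_scalar_number(fs) || fs <= 0) abort("`fs` must be a positive number")
  modality <- match.arg(modality, c("eeg", "nirs_intensity", "nirs_hb"))
  if (is.null(events)) {
    events <- tibble::tibble(onset = integer(), label = character())
  }
  events <- tibble::as_tibble(events)
  if (nrow(events) > 0) {
    if (!all(c("onset", "label") %in% names(events))) {
      abort("`events` needs columns `onset` and `label`")
    }
    events$onset <- as.integer(events$onset)
    events$label <- as.character(events$label)
    if (any(events$onset < 0L | events$onset >= ncol(signal))) {
      abort("event onsets must lie in [0, n_samples)")
    }
  }
  n_named <- length(channel_names)
  if (modality == "nirs_intensity") {
    if (is.null(wavelengths) || length(wavelengths) != 2) {
      abort("`nirs_intensity` recordings need exactly 2 wavelengths")
    }
    if (nrow(signal) != 2L * n_named) {
      abort("`nirs_intensity` signal must have 2 * n_channels rows (wavelength-major)")
    }
  } else {
    wavelengths <- NULL
    if (nrow(signal) != n_named) {
      abort("number of signal rows must match `channel_names`")
    }
  }
  structure(
    list(
      signal = signal, fs = fs,
      channel_names = as.character(channel_names),
      modality = modality, wavelengths = wavelengths, events = events
    ),
    class = "bci_recording"
  )
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf(
    "<bci_recording> %s: %d channel(s) x %d samples @ %g Hz, %d event(s)\n",
    x$modality, length(x$channel_names), ncol(x$signal), x$fs, nrow(x$events)
  ))
  invisible(x)
}

#' @export
dim.bci_recording <- function(x) dim(x$signal)

n_samples <- function(rec) ncol(rec$signal)

#' Epoched trial data
#'
#' Trials-by-channels-by-samples array with one class label per trial.
#' `window` records the epoch extent in seconds relative to instruction
#' onset (half-open).
#'
#' @param data numeric 3-d array `[n_trials, n_channels, n_samples]`.
#' @param fs sampling rate, Hz.
#' @param labels integer vector (0/1), one per trial.
#' @param window numeric length-2, epoch window in seconds.
#' @param channel_names character vector, one per channel row.
#' @param modality modality tag carried over from the recording.
#' @param parent_trial,subtask_index only for subtask sets: parent-trial
#'   index and 0-based position of each 1-s window within its trial.
#' @return `bci_epochs` object (subclass `bci_subtasks` when the window
#'   bookkeeping is present).
#' @export
epoch_set <- function(data, fs, labels, window, channel_names, modality,
                      parent_trial = NULL, subtask_index = NULL) {
  stopifnot(length(dim(data)) == 3)
  labels <- as.integer(labels)
  if (dim(data)[1] != length(labels)) {
    abort("number of trials must equal number of labels")
  }
  if (length(labels) > 0 && !all(labels %in% c(0L, 1L))) {
    abort("labels must be 0/1")
  }
  out <- structure(
    list(
      data = data, fs = fs, labels = labels, window = window,
      channel_names = as.character(channel_names), modality = modality
    ),
    class = "bci_epochs"
  )
  if (!is.null(parent_trial)) {
    out$parent_trial <- as.integer(parent_trial)
    out$subtask_index <- as.integer(subtask_index)
    class(out) <- c("bci_subtasks", class(out))
  }
  out
}

#' @export
print.bci_epochs <- function(x, ...) {
  kind <- if (inherits(x, "bci_subtasks")) "bci_subtasks" else "bci_epochs"
  cat(sprintf(
    "<%s> %s: %d trial(s) x %d channel(s) x %d samples @ %g Hz\n",
    kind, x$modality, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs
  ))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]
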