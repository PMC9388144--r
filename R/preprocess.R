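#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean over all EEG channels.
#'
#' @param rec an EEG [recording()] with at least 2 channels.
#' @return re-referenced recording; column means are 0 to rounding.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "bci_recording"))
  if (rec$modality != "eeg") abort("common average reference is defined for EEG")
  if (nrow(rec$signal) < 2L) abort("need at least 2 channels to re-reference")
  rec$signal <- sweep(rec$signal, 2L, colMeans(rec$signal))
  rec
}

#' Band-pass filter specification
#'
#' @param kind `"chebyshev2"` (applied forward-only) or `"butterworth"`.
#' @param order filter order of the analog prototype (a band-pass design
#'   doubles it in the digital filter).
#' @param band numeric length-2 pass band `(low, high)` in Hz.
#' @param zero_phase apply forward-backward (`filtfilt`)? The effective
#'   magnitude-response order doubles.
#' @param stopband_attenuation Chebyshev-II stop-band attenuation in dB.
#' @param stopband Chebyshev-II stop-band edges in Hz (the Chebyshev-II
#'   design is anchored at its stop band).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(kind = c("chebyshev2", "butterworth"), order, band,
                        zero_phase = FALSE, stopband_attenuation = 40,
                        stopband = NULL) {
  kind <- match.arg(kind)
  if (order < 1) abort("filter order must be >= 1")
  if (band[1] <= 0 || band[2] <= band[1]) abort("need 0 < low < high")
  if (kind == "chebyshev2" && is.null(stopband)) {
    stopband <- c(band[1] / 2, band[2] * 1.2)
  }
  structure(list(kind = kind, order = order, band = band,
                 zero_phase = zero_phase,
                 stopband_attenuation = stopband_attenuation,
                 stopband = stopband),
            class = "filter_spec")
}

# Digital filter coefficients for a spec at sampling rate fs.
design_filter <- function(spec, fs) {
  nyq <- fs / 2
  edges <- if (spec$kind == "chebyshev2") spec$stopband else spec$band
  if (any(edges >= nyq)) abort("filter band edge at or above Nyquist")
  if (spec$kind == "chebyshev2") {
    signal::cheby2(spec$order, spec$stopband_attenuation, edges / nyq, type = "pass")
  } else {
    signal::butter(spec$order, edges / nyq, type = "pass")
  }
}

# Forward-backward filtering with odd-reflection edge padding (signal::filtfilt
# alone zero-pads, which leaves large end transients on non-zero-mean data).
filtfilt_reflect <- function(ba, x, npad = 300L) {
  n <- length(x)
  npad <- min(n - 1L, npad)
  if (npad < 1L) return(signal::filtfilt(ba$b, ba$a, x))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filtfilt(ba$b, ba$a, xp)
  y[(npad + 1):(npad + n)]
}

#' Band-pass filter a recording
#'
#' EEG uses a forward-only Chebyshev type II band-pass (0.5-50 Hz by
#' default); chromophore fNIRS traces use a zero-phase (forward-backward)
#' Butterworth band-pass (0.01-0.09 Hz by default). Both designs come from
#' [filter_spec()].
#'
#' @param rec a [recording()].
#' @param spec a [filter_spec()].
#' @return filtered recording of the same shape and sampling rate.
#' @export
bandpass <- function(rec, spec) {
  stopifnot(inherits(rec, "bci_recording"), inherits(spec, "filter_spec"))
  ba <- design_filter(spec, rec$fs)
  rec$signal <- t(apply(rec$signal, 1L, function(x) {
    if (spec$zero_phase) filtfilt_reflect(ba, x)
    else as.numeric(signal::filter(ba, x))
  }))
  rec
}

#' Convenience filter constructors matching the default analysis chain
#' @rdname bandpass
#' @param fs sampling rate (unused; kept for symmetry).
#' @export
eeg_bandpass_spec <- function() {
  filter_spec("chebyshev2", order = 4, band = c(0.5, 50),
              zero_phase = FALSE, stopband_attenuation = 40,
              stopband = c(0.25, 60))
}

#' @rdname bandpass
#' @export
fnirs_bandpass_spec <- function() {
  filter_spec("butterworth", order = 3, band = c(0.01, 0.09), zero_phase = TRUE)
}

#' Downsample a recording
#'
#' Anti-alias filters (zero-phase 8th-order Butterworth low-pass at
#' `0.8 * fs_new / 2`) and resamples to any rational rate ratio by
#' zero-stuffed upsampling followed by decimation. Event onsets are
#' re-indexed with `floor(onset * fs_new / fs)`.
#'
#' @param rec a [recording()].
#' @param fs_new target sampling rate in Hz, strictly below `rec$fs`; the
#'   ratio `fs / fs_new` must be rational (e.g. 1000 -> 200, 12.5 -> 10).
#' @return downsampled recording with re-indexed events.
#' @export
downsample <- function(rec, fs_new) {
  stopifnot(inherits(rec, "bci_recording"))
  if (fs_new >= rec$fs) abort("`fs_new` must be below the current rate")
  frac <- rational_ratio(fs_new / rec$fs)
  p <- frac[1]; q <- frac[2]
  rec$signal <- t(apply(rec$signal, 1L, resample_pq, p = p, q = q))
  if (nrow(rec$events) > 0) {
    rec$events$onset <- as.integer(floor(rec$events$onset * fs_new / rec$fs))
  }
  rec$fs <- fs_new
  rec
}

# Smallest integers p/q with p/q == x (to tolerance); x in (0,1).
rational_ratio <- function(x, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9 && round(p) >= 1) return(c(round(p), q))
  }
  abort("resampling ratio is not a small rational number")
}

# Upsample by p (zero-stuffing, gain p), zero-phase low-pass, decimate by q.
resample_pq <- function(x, p, q) {
  n <- length(x)
  npad <- min(n - 1L, 300L)
  xp <- if (npad >= 1L) {
    c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  } else x
  if (p > 1L) {
    u <- numeric(length(xp) * p)
    u[seq(1L, length(u), by = p)] <- xp * p
  } else {
    u <- xp
  }
  ba <- signal::butter(8, 0.8 / max(p, q), type = "low")
  y <- signal::filtfilt(ba$b, ba$a, u)
  y <- y[(npad * p + 1):(npad * p + n * p)]
  y[seq(1L, length(y), by = q)]
}

#' Modified Beer-Lambert law parameters
#'
#' @param extinction 2x2 matrix of extinction coefficients, rows =
#'   wavelengths, columns = (HbO, Hb), units 1/(mM cm). Defaults are a
#'   standard tabulation for 760/850 nm; they are configuration, not ground
#'   truth.
#' @param dpf differential pathlength factor per wavelength (unitless).
#' @param distance source-detector separation in cm.
#' @return an `mbll_params` list.
#' @export
mbll_params <- function(extinction = matrix(c(0.586, 1.548, 1.058, 0.691),
                                            nrow = 2, byrow = TRUE,
                                            dimnames = list(c("760", "850"),
                                                            c("HbO", "Hb"))),
                        dpf = c(6.0, 6.0), distance = 3.0) {
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2))) abort("extinction must be 2x2")
  if (abs(det(extinction)) < 1e-10 * max(abs(extinction))^2) {
    abort("extinction matrix is singular")
  }
  if (distance <= 0 || any(dpf <= 0)) abort("distance and dpf must be positive")
  structure(list(extinction = extinction, dpf = dpf, distance = distance),
            class = "mbll_params")
}

#' Modified Beer-Lambert law conversion
#'
#' Converts raw dual-wavelength intensities to chromophore concentration
#' changes. Per channel and sample the optical density change is
#' `dOD_l = -log10(I_l(t) / mean baseline I_l)`, and
#' `(dHbO, dHb) = (distance * diag(dpf) * E)^-1 dOD` in mM, reported in
#' micromolar. Output rows are the HbO block followed by the Hb block.
#'
#' @param rec a `nirs_intensity` [recording()] (wavelength-major rows).
#' @param params [mbll_params()].
#' @param baseline_window half-open window `(t0, t1)` in seconds used for
#'   the reference intensity; `NULL` means the whole recording.
#' @return a `nirs_hb` recording, concentration changes in micromolar.
#' @export
mbll <- function(rec, params = mbll_params(), baseline_window = NULL) {
  stopifnot(inherits(rec, "bci_recording"), inherits(params, "mbll_params"))
  if (rec$modality != "nirs_intensity") abort("mbll() expects raw intensities")
  nc <- length(rec$channel_names)
  idx <- if (is.null(baseline_window)) seq_len(n_samples(rec)) else {
    lo <- floor(baseline_window[1] * rec$fs) + 1L
    hi <- floor(baseline_window[2] * rec$fs)
    if (lo < 1L || hi > n_samples(rec) || hi < lo) abort("baseline window outside recording")
    lo:hi
  }
  A <- params$distance * diag(params$dpf) %*% params$extinction
  Ainv <- solve(A)
  hb <- matrix(0, nrow = 2L * nc, ncol = n_samples(rec))
  for (ch in seq_len(nc)) {
    i1 <- rec$signal[ch, ]
    i2 <- rec$signal[nc + ch, ]
    if (any(i1 <= 0) || any(i2 <= 0)) abort("non-positive intensity sample")
    b1 <- mean(i1[idx]); b2 <- mean(i2[idx])
    dod <- rbind(-log10(i1 / b1), -log10(i2 / b2))
    conc <- Ainv %*% dod * 1000   # mM -> uM
    hb[ch, ] <- conc[1, ]
    hb[nc + ch, ] <- conc[2, ]
  }
  # channel rows: HbO block then Hb block, names tagged per chromophore
  recording(hb, fs = rec$fs,
            channel_names = c(paste0(rec$channel_names, "-HbO"),
                              paste0(rec$channel_names, "-Hb")),
            modality = "nirs_hb", events = rec$events)
}

# Forward model used by the synthetic generator and round-trip tests:
# concentrations (uM, HbO then Hb blocks) -> dual-wavelength intensities.
mbll_forward <- function(hbo, hb, params = mbll_params(), baseline_intensity = 1.0) {
  A <- params$distance * diag(params$dpf) %*% params$extinction
  dod <- A %*% rbind(hbo, hb) / 1000
  rbind(baseline_intensity * 10^(-dod[1, ]), baseline_intensity * 10^(-dod[2, ]))
}

#' Extract task-process epochs
#'
#' Cuts one epoch per labelled task event, covering the half-open window
#' `[0, instruction_s + task_s)` seconds from instruction onset. Events
#' whose epoch would run past the end of the recording are dropped with a
#' warning. Labels are mapped through `label_map` (events with unmapped
#' labels are ignored).
#'
#' @param rec a [recording()] with events.
#' @param instruction_s visual-instruction duration, seconds (default 2).
#' @param task_s task-execution duration, seconds (default 10).
#' @param label_map named integer vector mapping event labels to classes.
#' @return an [epoch_set()].
#' @export
extract_task_epochs <- function(rec, instruction_s = 2, task_s = 10,
                                label_map = c(L = 0L, R = 1L, REST = 0L, MA = 1L)) {
  stopifnot(inherits(rec, "bci_recording"))
  len <- as.integer(round((instruction_s + task_s) * rec$fs))
  ev <- rec$events[rec$events$label %in% names(label_map), , drop = FALSE]
  keep <- ev$onset + len <= n_samples(rec)
  if (any(!keep)) {
    warn(sprintf("%d truncated epoch(s) dropped at end of recording", sum(!keep)))
    ev <- ev[keep, , drop = FALSE]
  }
  nt <- nrow(ev)
  nc <- nrow(rec$signal)
  data <- array(0, dim = c(nt, nc, len))
  for (i in seq_len(nt)) {
    data[i, , ] <- rec$signal[, (ev$onset[i] + 1L):(ev$onset[i] + len), drop = FALSE]
  }
  epoch_set(data, fs = rec$fs,
            labels = unname(label_map[ev$label]),
            window = c(0, instruction_s + task_s),
            channel_names = if (rec$modality == "nirs_intensity") {
              paste0(rep(rec$channel_names, 2), "-wl", rep(1:2, each = length(rec$channel_names)))
            } else rec$channel_names,
            modality = rec$modality)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (the 2-s visual-instruction period by default). Idempotent.
#'
#' @param ep an [epoch_set()].
#' @param baseline half-open window `(t0, t1)` seconds relative to epoch start.
#' @return baseline-corrected epoch set.
#' @export
baseline_correct <- function(ep, baseline = c(0, 2)) {
  stopifnot(inherits(ep, "bci_epochs"))
  lo <- floor((baseline[1] - ep$window[1]) * ep$fs) + 1L
  hi <- floor((baseline[2] - ep$window[1]) * ep$fs)
  if (lo < 1L || hi > dim(ep$data)[3] || hi < lo) abort("baseline window outside epoch")
  bl <- apply(ep$data[, , lo:hi, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(bl, dim = dim(ep$data))
  ep
}

#' Segment epochs into 1-s subtasks
#'
#' Splits the 10-s task-execution period of every epoch into 10 contiguous,
#' non-overlapping, half-open 1-s windows (`[k, k+1)` seconds, k = 2..11
#' from instruction onset). Each subtask inherits the trial label; ordering
#' is trial-major, then subtask index. With the standard 3-session, 20-trial
#' protocol this yields 200 subtasks per session and 600 per subject.
#'
#' @param ep an [epoch_set()] covering at least `[task_start, task_start + task_s)`.
#' @param task_start task-execution onset in seconds from epoch start (default 2).
#' @param task_s task duration in seconds (default 10).
#' @return a subtask set (class `bci_subtasks`).
#' @export
segment_subtasks <- function(ep, task_start = 2, task_s = 10) {
  stopifnot(inherits(ep, "bci_epochs"))
  spf <- ep$fs * 1.0
  if (abs(spf - round(spf)) > 1e-9) abort("fs * 1 s must be an integer number of samples")
  spf <- as.integer(round(spf))
  n_sub <- as.integer(round(task_s))
  offset <- as.integer(round((task_start - ep$window[1]) * ep$fs))
  if (offset + n_sub * spf > dim(ep$data)[3]) abort("epoch does not cover the task period")
  nt <- n_trials(ep); nc <- dim(ep$data)[2]
  data <- array(0, dim = c(nt * n_sub, nc, spf))
  for (i in seq_len(nt)) {
    for (k in seq_len(n_sub)) {
      cols <- (offset + (k - 1L) * spf + 1L):(offset + k * spf)
      data[(i - 1L) * n_sub + k, , ] <- ep$data[i, , cols]
    }
  }
  epoch_set(data, fs = ep$fs,
            labels = rep(ep$labels, each = n_sub),
            window = c(task_start, task_start + task_s),
            channel_names = ep$channel_names, modality = ep$modality,
            parent_trial = rep(seq_len(nt), each = n_sub),
            subtask_index = rep(0:(n_sub - 1L), times = nt))
}

#' Peak-to-peak amplitude trial rejection
#'
#' Optional artifact screen (off by default in the pipelines): drops
#' subtasks whose peak-to-peak amplitude on any channel exceeds a
#' threshold (150 microvolts is a common EEG screen).
#'
#' @param sub a `bci_subtasks` set.
#' @param threshold peak-to-peak rejection threshold (signal units).
#' @return subtask set with offending subtasks removed.
#' @export
reject_amplitude <- function(sub, threshold = 150) {
  stopifnot(inherits(sub, "bci_subtasks"))
  ptp <- apply(sub$data, 1L, function(tr) max(apply(tr, 1L, function(x) diff(range(x)))))
  keep <- ptp <= threshold
  if (all(keep)) return(sub)
  warn(sprintf("rejected %d subtask(s) above %g peak-to-peak", sum(!keep), threshold))
  sub$data <- sub$data[keep, , , drop = FALSE]
  sub$labels <- sub$labels[keep]
  sub$parent_trial <- sub$parent_trial[keep]
  sub$subtask_index <- sub$subtask_index[keep]
  sub
}

#' Standard preprocessing chains
#'
#' `preprocess_eeg()`: common average reference -> 0.5-50 Hz Chebyshev-II
#' band-pass (forward-only) -> optional amplitude rejection -> downsample
#' to 200 Hz -> 12-s task epochs -> 1-s subtasks.
#'
#' `preprocess_fnirs()`: downsample to 10 Hz -> modified Beer-Lambert law
#' -> 0.01-0.09 Hz zero-phase Butterworth -> 12-s task epochs -> baseline
#' correction over the 2-s instruction period -> 1-s subtasks.
#'
#' @param rec raw [recording()] of the matching modality.
#' @param fs_target post-decimation sampling rate (Hz).
#' @param reject_threshold peak-to-peak rejection threshold in microvolts,
#'   or `NULL` (default) to disable the screen.
#' @param params [mbll_params()] for the chromophore conversion.
#' @param label_map event-label-to-class mapping, see [extract_task_epochs()].
#' @return a `bci_subtasks` set ready for feature extraction.
#' @export
preprocess_eeg <- function(rec, fs_target = 200, reject_threshold = NULL,
                           label_map = c(L = 0L, R = 1L, REST = 0L, MA = 1L)) {
  rec <- common_average_reference(rec)
  rec <- bandpass(rec, eeg_bandpass_spec())
  if (rec$fs > fs_target) rec <- downsample(rec, fs_target)
  sub <- segment_subtasks(extract_task_epochs(rec, label_map = label_map))
  if (!is.null(reject_threshold)) sub <- reject_amplitude(sub, reject_threshold)
  sub
}

#' @rdname preprocess_eeg
#' @export
preprocess_fnirs <- function(rec, fs_target = 10, params = mbll_params(),
                             label_map = c(L = 0L, R = 1L, REST = 0L, MA = 1L)) {
  if (rec$fs > fs_target) rec <- downsample(rec, fs_target)
  rec <- mbll(rec, params = params)
  rec <- bandpass(rec, fnirs_bandpass_spec())
  ep <- extract_task_epochs(rec, label_map = label_map)
  ep <- baseline_correct(ep, baseline = c(0, 2))
  segment_subtasks(ep)
}
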