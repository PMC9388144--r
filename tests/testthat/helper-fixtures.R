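# Shared fixture builders; everything is generated in code at test time.

# Minimal recording: channels x samples matrix of standard normals.
random_recording <- function(n_channels = 4, n_samples = 100, fs = 100,
                             modality = "eeg", seed = 1, events = NULL) {
  withr::with_seed(seed, {
    recording(matrix(rnorm(n_channels * n_samples), nrow = n_channels),
              fs = fs,
              channel_names = sprintf("CH%02d", seq_len(n_channels)),
              modality = modality, events = events)
  })
}

# Subtask set built directly from a list of per-subtask channel x sample
# matrices (bypasses the epoching chain for unit-level feature tests).
subtasks_from_matrices <- function(mats, fs, labels, modality = "eeg") {
  nc <- nrow(mats[[1]]); ns <- ncol(mats[[1]])
  data <- array(0, dim = c(length(mats), nc, ns))
  for (i in seq_along(mats)) data[i, , ] <- mats[[i]]
  epoch_set(data, fs = fs, labels = labels, window = c(2, 2 + length(mats)),
            channel_names = sprintf("CH%02d", seq_len(nc)), modality = modality,
            parent_trial = seq_along(mats),
            subtask_index = rep(0L, length(mats)))
}

# Feature matrix with `n_inf` informative columns (shifted by class) and
# `n_noise` pure-noise columns, z-scored.
informative_features <- function(n = 200, n_inf = 5, n_noise = 20,
                                 shift = 2, noise_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    inf <- matrix(rnorm(n * n_inf, sd = noise_sd), nrow = n) + shift * y
    noise <- matrix(rnorm(n * n_noise, sd = noise_sd), nrow = n)
    fm <- feature_matrix(cbind(inf, noise),
                         c(sprintf("inf%02d", seq_len(n_inf)),
                           sprintf("noise%02d", seq_len(n_noise))),
                         y, modality = "eeg", domain = "multi")
    zscore_apply(fm, zscore_fit(fm))
  })
}

# A recording with `n_events` labelled instruction onsets spaced evenly.
recording_with_events <- function(n_events = 60, fs = 100, epoch_s = 12,
                                  gap_s = 2, n_channels = 2, seed = 7) {
  spacing <- (epoch_s + gap_s) * fs
  onsets <- (seq_len(n_events) - 1L) * spacing
  n <- n_events * spacing
  labels <- rep(c("L", "R"), length.out = n_events)
  withr::with_seed(seed, {
    recording(matrix(rnorm(n_channels * n), nrow = n_channels), fs = fs,
              channel_names = sprintf("CH%02d", seq_len(n_channels)),
              modality = "eeg",
              events = tibble::tibble(onset = as.integer(onsets), label = labels))
  })
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max |diff| = %g (tol %g)",
                              max(abs(actual - expected)), tol))
}
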