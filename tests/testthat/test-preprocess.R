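test_that("common average reference zeroes the channel mean at every sample", {
  # constant signal collapses to zero
  rec <- recording(matrix(5, nrow = 3, ncol = 10), fs = 10,
                   channel_names = c("a", "b", "c"), modality = "eeg")
  expect_equal(common_average_reference(rec)$signal, matrix(0, 3, 10))
  # an already zero-mean pair is a fixed point
  rec2 <- recording(rbind(rep(1, 5), rep(-1, 5)), fs = 10,
                    channel_names = c("a", "b"), modality = "eeg")
  expect_equal(common_average_reference(rec2)$signal, rec2$signal)
  # random matrix: direct mean-subtraction oracle
  rec3 <- random_recording(4, 100, seed = 3)
  out <- common_average_reference(rec3)
  expect_lt(max(abs(colMeans(out$signal))), 1e-12)
  expect_equal(out$signal, sweep(rec3$signal, 2, colMeans(rec3$signal)))
  # single channel refuses
  rec1 <- recording(matrix(1, 1, 10), fs = 10, channel_names = "a", modality = "eeg")
  expect_error(common_average_reference(rec1), "2 channels")
})

test_that("Chebyshev-II band-pass passes 10 Hz and stops 90 Hz", {
  fs <- 200
  t <- (0:3999) / fs
  rec <- recording(matrix(sin(2 * pi * 10 * t), nrow = 1), fs = fs,
                   channel_names = "a", modality = "eeg")
  out <- bandpass(rec, eeg_bandpass_spec())
  gain <- sd(out$signal[1, 1000:3000]) / sd(rec$signal[1, 1000:3000])
  expect_gt(gain, 0.95); expect_lt(gain, 1.05)

  fs <- 1000
  t <- (0:9999) / fs
  rec <- recording(matrix(sin(2 * pi * 90 * t), nrow = 1), fs = fs,
                   channel_names = "a", modality = "eeg")
  out <- bandpass(rec, eeg_bandpass_spec())
  atten_db <- -20 * log10(sd(out$signal[1, 3000:9000]) / sd(rec$signal[1, 3000:9000]))
  expect_gte(atten_db, 30)

  # band edge at/above Nyquist refused
  rec <- random_recording(1, 100, fs = 100)
  expect_error(bandpass(rec, eeg_bandpass_spec()), "Nyquist")
})

test_that("zero-phase Butterworth introduces no group delay in band", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  x <- sin(2 * pi * 0.05 * t)
  rec <- recording(matrix(x, nrow = 1), fs = fs, channel_names = "a",
                   modality = "nirs_hb")
  out <- bandpass(rec, fnirs_bandpass_spec())
  cc <- stats::ccf(out$signal[1, ], x, lag.max = 30, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("downsample preserves DC, re-indexes events and keeps spectral peaks", {
  ev <- tibble::tibble(onset = 1000L, label = "L")
  rec <- recording(matrix(3, nrow = 1, ncol = 5000), fs = 1000,
                   channel_names = "a", modality = "eeg", events = ev)
  out <- downsample(rec, 200)
  expect_equal(ncol(out$signal), 1000L)
  expect_lt(max(abs(out$signal - 3)), 1e-6)
  expect_identical(out$events$onset, 200L)
  expect_identical(out$fs, 200)

  # spectral peak invariance, 5 Hz through 1000 -> 200 Hz
  t <- (0:9999) / 1000
  rec <- recording(matrix(sin(2 * pi * 5 * t), nrow = 1), fs = 1000,
                   channel_names = "a", modality = "eeg")
  y <- downsample(rec, 200)$signal[1, ]
  pg <- periodogram(y, fs = 200)
  half <- pg[pg$frequency <= 100, ]
  expect_equal(half$frequency[which.max(half$power)], 5, tolerance = 1e-6)

  # rational non-integer ratio (12.5 -> 10 Hz)
  rec <- recording(matrix(3, nrow = 1, ncol = 125), fs = 12.5,
                   channel_names = "a", modality = "nirs_hb")
  out <- downsample(rec, 10)
  expect_equal(ncol(out$signal), 100L)
  expect_lt(max(abs(out$signal - 3)), 1e-6)

  expect_error(downsample(rec, 20), "below")
})

test_that("modified Beer-Lambert law inverts its forward model", {
  p <- mbll_params()
  n <- 50
  # constant intensities -> zero concentration change
  rec <- recording(matrix(0.8, nrow = 4, ncol = n), fs = 10,
                   channel_names = c("a", "b"), modality = "nirs_intensity",
                   wavelengths = c(760, 850))
  hb <- mbll(rec, p)
  expect_equal(hb$modality, "nirs_hb")
  expect_equal(max(abs(hb$signal)), 0)
  expect_identical(hb$channel_names, c("a-HbO", "b-HbO", "a-Hb", "b-Hb"))

  # forward-simulate known concentrations, invert, compare
  hbo <- c(numeric(10), rep(1.0, 30), numeric(10))
  hbr <- c(numeric(10), rep(-0.5, 30), numeric(10))
  I <- hybridbci:::mbll_forward(hbo, hbr, p, baseline_intensity = 1)
  rec <- recording(rbind(I[1, ], I[2, ]), fs = 10, channel_names = "a",
                   modality = "nirs_intensity", wavelengths = c(760, 850))
  out <- mbll(rec, p, baseline_window = c(0, 1))
  expect_close(out$signal[1, ], hbo, tol = 1e-9)
  expect_close(out$signal[2, ], hbr, tol = 1e-9)

  # singular extinction matrix refused
  expect_error(mbll_params(extinction = matrix(c(1, 2, 2, 4), 2)), "singular")
  # non-positive intensities refused
  bad <- recording(matrix(c(rep(1, 10), rep(-1, 10)), nrow = 2, byrow = TRUE),
                   fs = 10, channel_names = "a", modality = "nirs_intensity",
                   wavelengths = c(760, 850))
  expect_error(mbll(bad, p), "intensity")
})

test_that("task epochs are cut per labelled event with boundary handling", {
  rec <- recording_with_events(n_events = 60, fs = 100)
  ep <- extract_task_epochs(rec)
  expect_equal(dim(ep$data), c(60, 2, 1200))
  expect_equal(sort(unique(ep$labels)), c(0L, 1L))

  # event too close to the end is dropped with a warning
  short <- rec
  short$signal <- short$signal[, 1:(59 * 1400 + 300), drop = FALSE]
  short$events <- short$events[short$events$onset < ncol(short$signal), ]
  expect_warning(ep2 <- extract_task_epochs(short), "truncated")
  expect_equal(dim(ep2$data)[1], 59)

  # no events -> empty epoch set
  none <- random_recording(2, 100, fs = 100)
  ep3 <- extract_task_epochs(none)
  expect_equal(dim(ep3$data)[1], 0)
})

test_that("baseline correction removes the instruction-period mean and is idempotent", {
  fs <- 10
  # constant epochs collapse to zero
  data <- array(5, dim = c(2, 1, 120))
  ep <- epoch_set(data, fs = fs, labels = c(0L, 1L), window = c(0, 12),
                  channel_names = "a", modality = "nirs_hb")
  out <- baseline_correct(ep)
  expect_equal(max(abs(out$data)), 0)

  # offset + ramp: the offset goes, the ramp survives
  t <- (0:119) / fs
  ramp <- ifelse(t >= 2, t - 2, 0)
  data <- array(rep(2 + ramp, each = 1), dim = c(1, 1, 120))
  ep <- epoch_set(data, fs = fs, labels = 0L, window = c(0, 12),
                  channel_names = "a", modality = "nirs_hb")
  out <- baseline_correct(ep)
  expect_close(out$data[1, 1, ], ramp, tol = 1e-12)
  # idempotent
  out2 <- baseline_correct(out)
  expect_equal(out2$data, out$data)

  expect_error(baseline_correct(ep, baseline = c(-5, -1)), "baseline")
})

test_that("subtask segmentation yields 10 contiguous 1-s windows per trial", {
  rec <- recording_with_events(n_events = 60, fs = 200, n_channels = 2)
  sub <- segment_subtasks(extract_task_epochs(rec))
  expect_equal(dim(sub$data), c(600, 2, 200))
  expect_identical(sub$labels, rep(extract_task_epochs(rec)$labels, each = 10))
  expect_identical(sub$subtask_index[1:10], 0:9)

  # one session's worth: 20 trials -> 200 subtasks
  rec20 <- recording_with_events(n_events = 20, fs = 200)
  expect_equal(dim(segment_subtasks(extract_task_epochs(rec20))$data)[1], 200)

  # single trial at 10 Hz -> 10 subtasks of 10 samples
  rec1 <- recording_with_events(n_events = 1, fs = 10)
  sub1 <- segment_subtasks(extract_task_epochs(rec1))
  expect_equal(dim(sub1$data), c(10, 2, 10))
  # windows tile the task period contiguously
  ep1 <- extract_task_epochs(rec1)
  expect_equal(as.vector(t(sub1$data[, 1, ])), ep1$data[1, 1, 21:120])

  # non-integer samples per second refused
  rec_frac <- recording_with_events(n_events = 1, fs = 2.5)
  expect_error(segment_subtasks(extract_task_epochs(rec_frac)), "integer")
})

test_that("amplitude rejection drops only offending subtasks", {
  mats <- list(matrix(rnorm(20), 2, 10), matrix(c(rnorm(10), 200, rnorm(9)), 2, 10, byrow = TRUE))
  sub <- subtasks_from_matrices(mats, fs = 10, labels = c(0L, 1L))
  expect_warning(out <- reject_amplitude(sub, 150), "rejected")
  expect_equal(dim(out$data)[1], 1)
  expect_identical(out$labels, 0L)
})
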