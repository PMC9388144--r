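#' Synthetic dataset configuration
#'
#' Parameters of the paired EEG + dual-wavelength fNIRS generator. The
#' default protocol mirrors the standard hybrid-BCI session structure:
#' 3 sessions of 20 task repetitions, each trial a 2-s visual instruction,
#' 10-s task execution and a 15-17 s rest, with balanced two-class labels.
#' EEG is generated at 250 Hz by default to keep simulations light;
#' `paper_rates = TRUE` switches to the 1000 Hz / 12.5 Hz acquisition
#' rates so the exact decimation ratios are exercised.
#'
#' The class signal is an event-related-desynchronisation surrogate for
#' EEG (task-locked attenuation of a common 10 Hz rhythm by `1 -
#' effect_size` on the class-dependent half of the channels over a 1/f
#' background) and a canonical double-gamma haemodynamic response for
#' fNIRS (HbO up on the class-dependent channel half, Hb = -HbO/3),
#' contaminated by cardiac (1 Hz), respiratory (0.2 Hz) and Mayer-wave
#' (0.1 Hz) oscillations plus white noise, all scaled by `noise_sd`, and
#' emitted as strictly positive raw intensities through the forward
#' modified Beer-Lambert law around baseline intensity 1.0.
#'
#' @param n_sessions number of sessions (default 3).
#' @param n_repetitions task repetitions per session (default 20).
#' @param fs_eeg,fs_nirs raw sampling rates, Hz.
#' @param n_eeg_channels,n_nirs_channels channel counts (defaults 30, 36).
#' @param effect_size class effect size `d >= 0`; 0 removes all class
#'   information.
#' @param noise_sd overall nuisance scale (1 = nominal physiological
#'   contamination).
#' @param task `"MI"` (labels L/R) or `"MA"` (labels REST/MA).
#' @param hbo_amplitude peak HbO response amplitude at `effect_size = 1`,
#'   micromolar.
#' @param paper_rates use 1000 Hz EEG / 12.5 Hz fNIRS acquisition rates.
#' @param seed RNG seed; generation is bit-reproducible from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_sessions = 3L, n_repetitions = 20L,
                         fs_eeg = 250, fs_nirs = 12.5,
                         n_eeg_channels = 30L, n_nirs_channels = 36L,
                         effect_size = 0.8, noise_sd = 1,
                         task = c("MI", "MA"), hbo_amplitude = 1,
                         paper_rates = FALSE, seed = 1L) {
  task <- match.arg(task)
  if (paper_rates) { fs_eeg <- 1000; fs_nirs <- 12.5 }
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (n_sessions < 1 || n_repetitions < 1) abort("counts must be positive")
  structure(list(n_sessions = as.integer(n_sessions),
                 n_repetitions = as.integer(n_repetitions),
                 fs_eeg = fs_eeg, fs_nirs = fs_nirs,
                 n_eeg_channels = as.integer(n_eeg_channels),
                 n_nirs_channels = as.integer(n_nirs_channels),
                 effect_size = effect_size, noise_sd = noise_sd,
                 task = task, hbo_amplitude = hbo_amplitude,
                 instruction_s = 2, task_s = 10, rest_range = c(15, 17),
                 session_pad_s = 15, seed = as.integer(seed)),
            class = "synth_config")
}

# Shared trial timeline in seconds: instruction onsets, balanced labels,
# per-trial rest durations and the total duration. Deterministic from the
# config seed, so the EEG and fNIRS streams agree event-for-event.
make_timeline <- function(cfg) {
  with_seed(stage_seed(cfg$seed, "timeline"), {
    onsets <- numeric(0); classes <- integer(0); session <- integer(0)
    t <- 0
    half <- cfg$n_repetitions %/% 2
    for (s in seq_len(cfg$n_sessions)) {
      t <- t + cfg$session_pad_s
      labs <- sample(c(rep(0L, half), rep(1L, cfg$n_repetitions - half)))
      for (r in seq_len(cfg$n_repetitions)) {
        onsets <- c(onsets, t)
        classes <- c(classes, labs[r])
        session <- c(session, s)
        t <- t + cfg$instruction_s + cfg$task_s + runif(1, cfg$rest_range[1], cfg$rest_range[2])
      }
      t <- t + cfg$session_pad_s
    }
    label_names <- if (cfg$task == "MI") c("L", "R") else c("REST", "MA")
    tibble::tibble(onset_s = onsets, class = classes,
                   label = label_names[classes + 1L], session = session,
                   total_s = t)
  })
}

# 1/f-amplitude-shaped Gaussian noise via spectral shaping (flat below f0).
# FFTs run at a 2-3-5-smooth padded length: R's mixed-radix FFT is
# quadratic at awkward (e.g. prime) lengths.
pink_noise <- function(n, fs, f0 = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- rnorm(m)
  X <- fft(x)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)                 # fold to two-sided frequencies
  scale <- 1 / sqrt(pmax(f, f0))
  y <- Re(fft(X * scale, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / sd(y)
}

# Linear convolution, zero-padded to a 2-3-5-smooth FFT length.
conv_open <- function(x, h) {
  n <- length(x) + length(h) - 1L
  m <- stats::nextn(n, c(2, 3, 5))
  y <- Re(fft(fft(c(x, numeric(m - length(x)))) *
                fft(c(h, numeric(m - length(h)))), inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Generate a synthetic EEG recording
#'
#' Continuous multichannel EEG: per-channel 1/f background plus white
#' noise and a common 10 Hz rhythm. During each task-execution window the
#' rhythm is attenuated by `1 - effect_size` on the second (class 0) or
#' first (class 1) half of the channels, emulating lateralised
#' event-related desynchronisation. Events carry the class labels.
#'
#' @param cfg a [synth_config()].
#' @return an `eeg` [recording()].
#' @export
generate_eeg <- function(cfg) {
  tl <- make_timeline(cfg)
  fs <- cfg$fs_eeg
  n <- as.integer(floor(tl$total_s[1] * fs))
  nc <- cfg$n_eeg_channels
  tt <- (seq_len(n) - 1) / fs
  # task-window gain masks per class: 1 everywhere, 1 - d inside task windows
  gain0 <- rep(1, n); gain1 <- rep(1, n)
  for (i in seq_len(nrow(tl))) {
    a <- tl$onset_s[i] + cfg$instruction_s
    idx <- which(tt >= a & tt < a + cfg$task_s)
    if (tl$class[i] == 0L) gain0[idx] <- 1 - cfg$effect_size
    else gain1[idx] <- 1 - cfg$effect_size
  }
  sig <- matrix(0, nrow = nc, ncol = n)
  with_seed(stage_seed(cfg$seed, "eeg"), {
    for (ch in seq_len(nc)) {
      rhythm <- sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
      gain <- if (ch <= nc %/% 2) gain1 else gain0   # class 1 dampens left half
      sig[ch, ] <- cfg$noise_sd * (rnorm(n) + 0.5 * pink_noise(n, fs)) +
        1.5 * gain * rhythm
    }
  })
  recording(sig, fs = fs, channel_names = sprintf("EEG%02d", seq_len(nc)),
            modality = "eeg",
            events = tibble::tibble(onset = as.integer(floor(tl$onset_s * fs)),
                                    label = tl$label))
}

# Canonical double-gamma HRF (peaks ~6 s and ~16 s, undershoot ratio 1/6),
# unit peak amplitude.
hrf_kernel <- function(fs, dur = 30) {
  t <- seq(0, dur, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) - stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Generate a synthetic raw-intensity fNIRS recording
#'
#' Builds chromophore traces per channel -- a class-dependent double-gamma
#' haemodynamic response (HbO positive, Hb = -HbO/3) on the responsive
#' channel half, plus cardiac/respiratory/Mayer oscillations and white
#' noise scaled by `noise_sd` -- and converts them to strictly positive
#' dual-wavelength intensities with the forward modified Beer-Lambert law
#' (baseline intensity 1.0, wavelength-major row order).
#'
#' @param cfg a [synth_config()].
#' @param params [mbll_params()] used by the forward model.
#' @return a `nirs_intensity` [recording()].
#' @export
generate_fnirs <- function(cfg, params = mbll_params()) {
  tl <- make_timeline(cfg)
  fs <- cfg$fs_nirs
  n <- as.integer(floor(tl$total_s[1] * fs))
  nc <- cfg$n_nirs_channels
  tt <- (seq_len(n) - 1) / fs
  # per-class task boxcars convolved with the canonical HRF
  resp <- matrix(0, nrow = 2, ncol = n)
  for (cl in 0:1) {
    box <- rep(0, n)
    for (i in which(tl$class == cl)) {
      a <- tl$onset_s[i] + cfg$instruction_s
      box[tt >= a & tt < a + cfg$task_s] <- 1
    }
    h <- hrf_kernel(fs)
    conv <- conv_open(box, h)[seq_len(n)]
    resp[cl + 1L, ] <- conv / max(abs(conv))
  }
  hbo <- matrix(0, nrow = nc, ncol = n)
  hb <- matrix(0, nrow = nc, ncol = n)
  A <- cfg$hbo_amplitude * cfg$effect_size
  with_seed(stage_seed(cfg$seed, "nirs"), {
    for (ch in seq_len(nc)) {
      cl <- if (ch <= nc %/% 2) 0L else 1L
      physio <- 0.2 * sin(2 * pi * 1.0 * tt + runif(1, 0, 2 * pi)) +
        0.15 * sin(2 * pi * 0.2 * tt + runif(1, 0, 2 * pi)) +
        0.25 * sin(2 * pi * 0.1 * tt + runif(1, 0, 2 * pi))
      hbo[ch, ] <- A * resp[cl + 1L, ] + cfg$noise_sd * (physio + 0.1 * rnorm(n))
      hb[ch, ] <- -A * resp[cl + 1L, ] / 3 +
        cfg$noise_sd * (physio / 3 + 0.05 * rnorm(n))
    }
  })
  sig <- matrix(0, nrow = 2L * nc, ncol = n)
  for (ch in seq_len(nc)) {
    I <- mbll_forward(hbo[ch, ], hb[ch, ], params = params, baseline_intensity = 1.0)
    sig[ch, ] <- I[1, ]
    sig[nc + ch, ] <- I[2, ]
  }
  recording(sig, fs = fs, channel_names = sprintf("CH%02d", seq_len(nc)),
            modality = "nirs_intensity", wavelengths = c(760, 850),
            events = tibble::tibble(onset = as.integer(floor(tl$onset_s * fs)),
                                    label = tl$label))
}

#' Generate a paired synthetic EEG + fNIRS dataset
#'
#' Both streams share one trial timeline (identical event sequence and
#' balanced labels), so downstream epochs pair row-for-row. The returned
#' `truth` record carries the injected parameters for recovery tests.
#'
#' @param cfg a [synth_config()].
#' @param params [mbll_params()] for the fNIRS forward model.
#' @return list with `eeg`, `nirs` recordings and a `truth` list
#'   (`timeline` tibble + generator parameters).
#' @export
generate_dataset <- function(cfg = synth_config(), params = mbll_params()) {
  tl <- make_timeline(cfg)
  list(
    eeg = generate_eeg(cfg),
    nirs = generate_fnirs(cfg, params = params),
    truth = list(timeline = tl[setdiff(names(tl), "total_s")],
                 effect_size = cfg$effect_size,
                 hbo_amplitude = cfg$hbo_amplitude,
                 noise_sd = cfg$noise_sd, config = cfg)
  )
}
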