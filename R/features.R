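#' Periodogram power spectrum
#'
#' Plain periodogram `P(w) = |X_N(w)|^2 / N` where `X_N` is the discrete
#' Fourier transform of the length-`N` signal, optionally evaluated on a
#' zero-padded grid. On the unpadded grid the estimate satisfies Parseval's
#' identity exactly: `sum_k P(w_k) == sum_n x(n)^2`.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz (sets the frequency grid).
#' @param nfft DFT length; `NULL` uses `length(x)` (unpadded).
#' @return tibble with columns `frequency` (Hz, full 0..fs grid) and `power`.
#' @export
periodogram <- function(x, fs = 1, nfft = NULL) {
  n <- length(x)
  if (n < 1) abort("empty signal")
  if (is.null(nfft)) nfft <- n
  xp <- if (nfft > n) c(x, numeric(nfft - n)) else x[seq_len(nfft)]
  p <- Mod(fft(xp))^2 / n
  tibble::tibble(frequency = (seq_len(nfft) - 1) * fs / nfft, power = p)
}

# Hann-tapered periodogram with the taper power compensated so white noise
# of variance s2 has flat expected level s2. Returns frequency/power.
tapered_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xc <- (x - mean(x)) * w
  p <- Mod(fft(xc))^2 / (n * mean(w^2))
  tibble::tibble(frequency = (seq_len(n) - 1) * fs / n, power = p)
}

#' Time-domain statistic features
#'
#' Six statistics per channel of every 1-s subtask: mean
#' `mu = sum(x)/N`, population variance `sigma2 = sum((x-mu)^2)/N`, mean
#' absolute first difference `delta = sum(|x[n+1]-x[n]|)/(N-1)`, its
#' standard-deviation-normalised version `delta/sigma`, mean absolute
#' second difference `gamma = sum(|x[n+2]-x[n]|)/(N-2)` and `gamma/sigma`.
#' For a constant subtask (`sigma == 0`) the normalised statistics are 0.
#'
#' @param sub a `bci_subtasks` set with at least 3 samples per subtask.
#' @return a [feature_matrix()] with `6 * n_channels` columns, names
#'   `"<channel>.<statistic>"`, domain `"time"`.
#' @export
statistic_features <- function(sub) {
  stopifnot(inherits(sub, "bci_subtasks"))
  if (dim(sub$data)[3] < 3L) abort("subtasks must hold at least 3 samples")
  stats6 <- function(x) {
    n <- length(x)
    mu <- mean(x)
    s2 <- mean((x - mu)^2)
    s <- sqrt(s2)
    d1 <- sum(abs(diff(x))) / (n - 1)
    d2 <- sum(abs(x[-(1:2)] - x[seq_len(n - 2)])) / (n - 2)
    c(mu, s2, d1, if (s > 0) d1 / s else 0, d2, if (s > 0) d2 / s else 0)
  }
  nt <- n_trials(sub); nc <- dim(sub$data)[2]
  vals <- matrix(0, nrow = nt, ncol = 6L * nc)
  for (i in seq_len(nt)) {
    m <- array(sub$data[i, , ], dim = dim(sub$data)[2:3])
    vals[i, ] <- as.vector(apply(m, 1L, stats6))
  }
  stat_names <- c("mean", "var", "diff1", "ndiff1", "diff2", "ndiff2")
  feature_matrix(vals,
                 paste(rep(sub$channel_names, each = 6L), stat_names, sep = "."),
                 sub$labels, modality = sub$modality, domain = "time")
}

#' Differential entropy features
#'
#' For each channel of every subtask the band-limited variance is estimated
#' as the mean Hann-tapered periodogram power over the requested band
#' (0.5-45 Hz by default), and the differential entropy of a Gaussian
#' source of that variance is reported in nats:
#' `DE = log(2 * pi * e * sigma2) / 2`. Bands whose upper edge exceeds the
#' Nyquist frequency are clipped with a warning; a zero variance estimate
#' is floored at machine epsilon with a warning. `sub_bands` may name a
#' list of `(low, high)` pairs (e.g. canonical delta/theta/alpha/beta/gamma)
#' to emit one column per channel per band.
#'
#' @param sub an EEG `bci_subtasks` set.
#' @param band default single analysis band `(low, high)` in Hz.
#' @param sub_bands optional named list of bands overriding `band`.
#' @return a [feature_matrix()] with one column per channel per band,
#'   domain `"freq"`.
#' @export
de_feature <- function(sub, band = c(0.5, 45), sub_bands = NULL) {
  stopifnot(inherits(sub, "bci_subtasks"))
  bands <- if (is.null(sub_bands)) list(de = band) else sub_bands
  nyq <- sub$fs / 2
  bands <- lapply(bands, function(b) {
    if (b[2] > nyq) {
      warn(sprintf("band upper edge %g Hz clipped to Nyquist %g Hz", b[2], nyq))
      b[2] <- nyq
    }
    b
  })
  nt <- n_trials(sub); nc <- dim(sub$data)[2]
  vals <- matrix(0, nrow = nt, ncol = nc * length(bands))
  floored <- FALSE
  for (i in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      pg <- tapered_periodogram(sub$data[i, ch, ], sub$fs)
      for (bi in seq_along(bands)) {
        b <- bands[[bi]]
        mask <- pg$frequency >= b[1] & pg$frequency <= b[2]
        s2 <- mean(pg$power[mask])
        if (!is.finite(s2) || s2 <= 0) {
          s2 <- .Machine$double.eps
          floored <- TRUE
        }
        vals[i, (bi - 1L) * nc + ch] <- 0.5 * log(2 * pi * exp(1) * s2)
      }
    }
  }
  if (floored) warn("zero band variance floored at machine epsilon")
  feature_matrix(vals,
                 as.vector(outer(sub$channel_names, names(bands),
                                 function(ch, b) paste(ch, "de", b, sep = "."))),
                 sub$labels, modality = sub$modality, domain = "freq")
}

#' Periodogram PSD features for chromophore signals
#'
#' Per channel (HbO and Hb rows alike) of every subtask: the periodogram
#' `P(w) = |DFT(x)|^2 / N` is evaluated on a zero-padded grid
#' (`nfft = 1024` by default) and the feature is the mean of `P` over the
#' requested band (0.01-0.1 Hz by default, the low-frequency hemodynamic
#' range). With `scope = "epoch"` the PSD is computed once over each parent
#' trial's full concatenated task period and assigned to all of its
#' subtasks.
#'
#' @param sub a `nirs_hb` `bci_subtasks` set.
#' @param band analysis band `(low, high)` in Hz.
#' @param nfft zero-padded DFT length.
#' @param scope `"subtask"` (default) or `"epoch"`.
#' @return a [feature_matrix()] with one column per channel row, domain
#'   `"freq"`.
#' @export
psd_feature <- function(sub, band = c(0.01, 0.1), nfft = 1024,
                        scope = c("subtask", "epoch")) {
  stopifnot(inherits(sub, "bci_subtasks"))
  scope <- match.arg(scope)
  nt <- n_trials(sub); nc <- dim(sub$data)[2]
  band_mean <- function(x) {
    pg <- periodogram(x, fs = sub$fs, nfft = max(nfft, length(x)))
    mask <- pg$frequency >= band[1] & pg$frequency <= band[2]
    if (!any(mask)) abort("no spectral grid point inside the analysis band")
    mean(pg$power[mask])
  }
  vals <- matrix(0, nrow = nt, ncol = nc)
  if (scope == "subtask") {
    for (i in seq_len(nt)) {
      for (ch in seq_len(nc)) vals[i, ch] <- band_mean(sub$data[i, ch, ])
    }
  } else {
    for (tr in unique(sub$parent_trial)) {
      rows <- which(sub$parent_trial == tr)
      rows <- rows[order(sub$subtask_index[rows])]
      for (ch in seq_len(nc)) {
        x <- as.vector(t(sub$data[rows, ch, , drop = FALSE][, 1, ]))
        vals[rows, ch] <- band_mean(x)
      }
    }
  }
  feature_matrix(vals, paste(sub$channel_names, "psd", sep = "."),
                 sub$labels, modality = sub$modality, domain = "freq")
}

#' Z-score normalisation
#'
#' `zscore_fit()` estimates per-feature mean and population standard
#' deviation on a fit partition (all rows by default); `zscore_apply()`
#' maps any matching feature matrix through `(x - mu) / sigma`. Constant
#' columns (`sigma == 0`) map to 0, so no non-finite values can appear.
#' Fitting on the training rows only keeps test information out of the
#' normaliser.
#'
#' @param fm a [feature_matrix()].
#' @param fit_rows integer row indices to estimate on (default: all rows).
#' @return `zscore_fit()` a `zscore_model`; `zscore_apply()` a normalised
#'   feature matrix.
#' @export
zscore_fit <- function(fm, fit_rows = NULL) {
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(fm))
  if (length(fit_rows) == 0) abort("`fit_rows` must be non-empty")
  vals <- feature_values(fm)[fit_rows, , drop = FALSE]
  mu <- colMeans(vals)
  sigma <- sqrt(colMeans(sweep(vals, 2L, mu)^2))
  structure(list(mean = mu, sd = sigma, features = feature_names(fm)),
            class = "zscore_model")
}

#' @rdname zscore_fit
#' @param model a `zscore_model` from `zscore_fit()`.
#' @export
zscore_apply <- function(fm, model) {
  stopifnot(inherits(model, "zscore_model"))
  if (!identical(feature_names(fm), model$features)) {
    abort("feature names do not match the fitted model")
  }
  vals <- sweep(feature_values(fm), 2L, model$mean)
  sd_safe <- ifelse(model$sd > 0, model$sd, 1)
  vals <- sweep(vals, 2L, sd_safe, "/")
  vals[, model$sd == 0] <- 0
  out <- feature_matrix(vals, model$features, feature_labels(fm),
                        modality = attr(fm, "modality"), domain = attr(fm, "domain"))
  assert_no_nonfinite(out, "z-scoring")
}
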