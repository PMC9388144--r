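#' @importFrom rlang abort warn .data
#' @importFrom stats fft sd var predict glm binomial rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Run code under a temporary RNG state; never touches the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-stage seed fan-out from one global seed. Offsets are fixed
# so each stage is independently reproducible; results stay below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    synth = 0L, timeline = 11L, eeg = 23L, nirs = 37L,
    zscore = 53L, aso_eeg = 101L, aso_nirs = 103L,
    fusion = 211L, splice = 307L, cv = 401L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown seed stage '", stage, "'"))
  }
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

# Stratified fold assignment: returns an integer fold id per row, each class
# spread as evenly as possible across folds.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# element-wise clamp that preserves matrix dimensions
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
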