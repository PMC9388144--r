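#' Fusion configuration
#'
#' Settings for the two-stage progressive-learning fusion: an ordered
#' registry of primary learners (4 by default, see [learner_registry()]),
#' a logistic-regression secondary learner, the 8:2 train/test split, 8
#' stratified folds for out-of-fold meta-features, and the number of
#' independent split repetitions reported.
#'
#' @param learners named list of learner definitions.
#' @param split_ratio training fraction of the outer split (default 0.8).
#' @param n_folds number of stacking folds `k` (default 8).
#' @param n_repetitions number of independent outer splits to average.
#' @param meta `"prob"` (positive-class probabilities, default) or
#'   `"labels"` (hard 0/1 predictions) as meta-features.
#' @param seed base RNG seed; repetition `r` uses `seed + r - 1`.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(learners = learner_registry(), split_ratio = 0.8,
                          n_folds = 8L, n_repetitions = 5L,
                          meta = c("prob", "labels"), seed = 1L) {
  if (length(learners) < 1) abort("need at least one primary learner")
  if (n_folds < 2) abort("need at least 2 folds")
  if (split_ratio <= 0 || split_ratio >= 1) abort("split_ratio must be in (0,1)")
  structure(list(learners = learners, split_ratio = split_ratio,
                 n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 meta = match.arg(meta), seed = as.integer(seed)),
            class = "fusion_config")
}

#' Stratified train/test split
#'
#' Seeded, stratified 80/20 split (class proportions preserved to within
#' one sample). The same indices are reused for both modalities of a
#' paired dataset.
#'
#' @param labels integer class labels (0/1).
#' @param split_ratio training fraction.
#' @param seed RNG seed.
#' @return list with integer vectors `train` and `test`.
#' @export
split_train_test <- function(labels, split_ratio = 0.8, seed = 1L) {
  classes <- unique(labels)
  if (any(table(labels) < 2)) abort("need at least 2 samples per class")
  train <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      ntr <- round(split_ratio * length(idx))
      train <- c(train, sort(sample(idx, ntr)))
    }
  })
  train <- sort(train)
  test <- setdiff(seq_along(labels), train)
  if (length(unique(labels[train])) < 2 || length(unique(labels[test])) < 2) {
    abort("a class is absent from one side of the split")
  }
  list(train = train, test = test)
}

#' Primary (first-level) learning for one modality
#'
#' For each learner: the training rows are split into `k = 8` stratified
#' folds; each fold in turn is held out, the learner is fitted on the
#' remaining 7 and predicts the held-out rows, assembling an out-of-fold
#' prediction column `A_t` in original row order. Each of the 8 fold
#' models also predicts the 20% test rows; their average forms `B_t`.
#' Folds that would contain a single class are redrawn with the next seed
#' (at most 10 attempts).
#'
#' @param fm one modality's selected [feature_matrix()].
#' @param train_idx,test_idx outer split indices from [split_train_test()].
#' @param cfg a [fusion_config()].
#' @return list with matrices `A` (`n_train x T`), `B` (`n_test x T`),
#'   column names `learners`, and the fitted fold `models`.
#' @export
primary_learn <- function(fm, train_idx, test_idx, cfg = fusion_config()) {
  x <- feature_values(fm); y <- feature_labels(fm)
  xtr <- x[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  xte <- x[test_idx, , drop = FALSE]
  k <- cfg$n_folds
  folds <- draw_folds(ytr, k, cfg$seed)
  T <- length(cfg$learners)
  A <- matrix(NA_real_, nrow = length(train_idx), ncol = T)
  B <- matrix(0, nrow = length(test_idx), ncol = T)
  models <- vector("list", T)
  for (t in seq_len(T)) {
    lrn <- cfg$learners[[t]]
    fold_models <- vector("list", k)
    for (i in seq_len(k)) {
      held <- folds == i
      fit <- lrn$fit(xtr[!held, , drop = FALSE], ytr[!held],
                     seed = cfg$seed + t)
      pa <- lrn$predict_prob(fit, xtr[held, , drop = FALSE])
      pb <- lrn$predict_prob(fit, xte)
      if (cfg$meta == "labels") { pa <- as.numeric(pa > 0.5); pb <- as.numeric(pb > 0.5) }
      A[held, t] <- pa
      B[, t] <- B[, t] + pb / k
      fold_models[[i]] <- fit
    }
    models[[t]] <- fold_models
  }
  list(A = A, B = B, learners = names(cfg$learners), models = models)
}

# Stratified folds, redrawn (next seed) while any fold is single-class.
draw_folds <- function(y, k, seed, max_attempts = 10L) {
  for (a in seq_len(max_attempts)) {
    folds <- stratified_folds(y, k, seed + a - 1L)
    ok <- all(vapply(seq_len(k), function(i) {
      length(unique(y[folds == i])) == 2L
    }, logical(1)))
    if (ok) {
      if (a > 1L) warn(sprintf("folds redrawn %d time(s) to keep both classes per fold", a - 1L))
      return(folds)
    }
  }
  abort("could not draw stratified folds with both classes in every fold")
}

#' Secondary (meta-level) learning
#'
#' Fits a logistic regression on the out-of-fold meta-feature matrix `A`
#' (columns EEG_A1..A4 then fNIRS_A1..A4 for the fused model) against the
#' training labels, and evaluates it on the fold-averaged test matrix `B`.
#' A constant meta-feature matrix degenerates to the majority class.
#'
#' @param A,B meta-feature matrices with matching column order.
#' @param labels_train,labels_test integer labels for the rows of `A`/`B`.
#' @return list with the fitted `model`, `predicted` labels and `accuracy`.
#' @export
secondary_learn <- function(A, B, labels_train, labels_test) {
  stopifnot(ncol(A) == ncol(B))
  dtr <- as.data.frame(A); names(dtr) <- paste0("m", seq_len(ncol(A)))
  dte <- as.data.frame(B); names(dte) <- names(dtr)
  dtr$.y <- labels_train
  model <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
  prob <- suppressWarnings(predict(model, newdata = dte, type = "response"))
  if (all(apply(A, 2L, function(col) diff(range(col)) == 0))) {
    maj <- as.integer(mean(labels_train) >= 0.5)
    predicted <- rep(maj, length(labels_test))
  } else {
    predicted <- as.integer(prob > 0.5)
  }
  list(model = model, predicted = predicted,
       accuracy = mean(predicted == labels_test))
}

#' Decision-level fusion by multi-level progressive learning
#'
#' Full two-modality stacking: for each repetition an 8:2 stratified split
#' (shared by both modalities) feeds [primary_learn()] per modality; the
#' EEG and fNIRS meta-feature blocks are concatenated (EEG columns first)
#' and a logistic-regression secondary learner produces the fused test
#' accuracy. Reports per-repetition accuracies with their mean and
#' standard deviation.
#'
#' @param eeg_fm,fnirs_fm paired selected feature matrices: identical row
#'   order and labels.
#' @param cfg a [fusion_config()].
#' @return a `bci_fusion` object; see [tidy.bci_fusion()],
#'   [glance.bci_fusion()], [autoplot.bci_fusion()].
#' @export
fuse <- function(eeg_fm, fnirs_fm, cfg = fusion_config()) {
  if (!identical(feature_labels(eeg_fm), feature_labels(fnirs_fm))) {
    abort("paired modalities must share labels and row order")
  }
  y <- feature_labels(eeg_fm)
  accs <- numeric(cfg$n_repetitions)
  last <- NULL
  for (r in seq_len(cfg$n_repetitions)) {
    rcfg <- cfg; rcfg$seed <- cfg$seed + r - 1L
    split <- split_train_test(y, cfg$split_ratio, rcfg$seed)
    pe <- primary_learn(eeg_fm, split$train, split$test, rcfg)
    pf <- primary_learn(fnirs_fm, split$train, split$test, rcfg)
    A <- cbind(pe$A, pf$A)
    B <- cbind(pe$B, pf$B)
    colnames(A) <- colnames(B) <- c(paste0("EEG_A", seq_along(pe$learners)),
                                    paste0("fNIRS_A", seq_along(pf$learners)))
    sec <- secondary_learn(A, B, y[split$train], y[split$test])
    accs[r] <- sec$accuracy
    last <- list(split = split, primary_eeg = pe, primary_fnirs = pf,
                 secondary = sec$model)
  }
  structure(
    list(accuracies = accs, mean = mean(accs),
         sd = if (length(accs) > 1) sd(accs) else 0,
         model = last, config = cfg),
    class = "bci_fusion"
  )
}

#' @export
print.bci_fusion <- function(x, ...) {
  cat(sprintf("<bci_fusion> %d repetition(s): accuracy %.4f +/- %.4f\n",
              length(x$accuracies), x$mean, x$sd))
  invisible(x)
}

#' Direct-splicing baseline
#'
#' The conventional feature-level fusion baseline: EEG and fNIRS feature
#' columns are concatenated ("simple matrix splicing") and classified by
#' the random-forest learner under stratified 8-fold cross-validation.
#'
#' @param eeg_fm,fnirs_fm paired feature matrices.
#' @param cfg a [fusion_config()] (folds and seed are used).
#' @return mean cross-validated accuracy.
#' @export
direct_splice_baseline <- function(eeg_fm, fnirs_fm, cfg = fusion_config()) {
  if (!identical(feature_labels(eeg_fm), feature_labels(fnirs_fm))) {
    abort("paired modalities must share labels and row order")
  }
  x <- cbind(feature_values(eeg_fm), feature_values(fnirs_fm))
  rf_cv_accuracy(x, feature_labels(eeg_fm), k = cfg$n_folds, seed = cfg$seed)
}

#' Single-matrix cross-validated accuracy
#'
#' Random-forest accuracy of one feature matrix under stratified k-fold
#' cross-validation; the per-condition classifier used in the comparison
#' report.
#'
#' @param fm a [feature_matrix()].
#' @param n_folds number of folds (default 8).
#' @param seed RNG seed.
#' @return mean cross-validated accuracy.
#' @export
modality_cv_accuracy <- function(fm, n_folds = 8L, seed = 1L) {
  rf_cv_accuracy(feature_values(fm), feature_labels(fm), k = n_folds, seed = seed)
}

#' Comparison report table
#'
#' Assembles per-subject, per-condition accuracies into a wide table with
#' `mean` and `sd` summary rows appended.
#'
#' @param results tibble/data frame with columns `subject`, `condition`,
#'   `accuracy`.
#' @return wide tibble: one row per subject plus `mean` and `sd` rows.
#' @export
evaluate_report <- function(results) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) abort("no results to report")
  wide <- tidyr::pivot_wider(results, id_cols = "subject",
                             names_from = "condition", values_from = "accuracy")
  conds <- setdiff(names(wide), "subject")
  mrow <- c(list(subject = "mean"), lapply(wide[conds], mean))
  srow <- c(list(subject = "sd"),
            lapply(wide[conds], function(v) if (length(v) > 1) sd(v) else 0))
  dplyr::bind_rows(wide, tibble::as_tibble(mrow), tibble::as_tibble(srow))
}
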