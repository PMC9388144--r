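test_that("the outer split is stratified, seeded and refuses degenerate classes", {
  labels <- rep(0:1, each = 300)
  sp <- split_train_test(labels, 0.8, seed = 4)
  expect_length(sp$train, 480)
  expect_length(sp$test, 120)
  expect_equal(sum(labels[sp$train]), 240)
  expect_equal(sum(labels[sp$test]), 60)
  expect_identical(sp, split_train_test(labels, 0.8, seed = 4))
  expect_false(identical(sp$train, split_train_test(labels, 0.8, seed = 5)$train))
  expect_error(split_train_test(c(0L, 0L, 0L, 1L), 0.8), "2 samples")
})

test_that("primary learning reproduces a hand-computed stacking oracle", {
  # 16 training samples, 4 test samples, k = 8 folds, stub learner that
  # predicts its fold-training-label mean.
  withr::with_seed(10, {
    x <- matrix(rnorm(20 * 2), ncol = 2)
  })
  y <- rep(c(0L, 1L), 10)
  fm <- feature_matrix(x, c("f1", "f2"), y)
  cfg <- fusion_config(learners = list(stub = hybridbci:::stub_learner()),
                       n_folds = 8, seed = 3)
  train_idx <- 1:16; test_idx <- 17:20
  res <- primary_learn(fm, train_idx, test_idx, cfg)
  expect_equal(dim(res$A), c(16, 1))
  expect_equal(dim(res$B), c(4, 1))

  # independent oracle: recompute folds and the per-fold label means
  folds <- hybridbci:::draw_folds(y[train_idx], 8, cfg$seed)
  expected_A <- vapply(seq_along(train_idx), function(i) {
    mean(y[train_idx][folds != folds[i]])
  }, numeric(1))
  expect_equal(as.numeric(res$A), expected_A)
  expected_B <- mean(vapply(1:8, function(f) mean(y[train_idx][folds != f]),
                            numeric(1)))
  expect_equal(as.numeric(res$B), rep(expected_B, 4))
})

test_that("out-of-fold predictions never come from a model that saw the row", {
  # memorising learner: predicts 1 exactly when the query row was in its
  # training set
  memoriser <- list(
    fit = function(x, y, seed) list(train = x),
    predict_prob = function(model, x) {
      keys <- apply(model$train, 1, paste, collapse = ",")
      as.numeric(apply(x, 1, paste, collapse = ",") %in% keys)
    }
  )
  withr::with_seed(12, { x <- matrix(rnorm(40 * 3), ncol = 3) })
  y <- rep(0:1, 20)
  fm <- feature_matrix(x, c("a", "b", "c"), y)
  cfg <- fusion_config(learners = list(mem = memoriser), n_folds = 8, seed = 1)
  res <- primary_learn(fm, 1:32, 33:40, cfg)
  expect_equal(max(res$A), 0)   # no training row predicted by its own model
  expect_equal(max(res$B), 0)   # test rows never enter primary training
})

test_that("fused accuracy is invariant to feature-column permutation with a stub", {
  withr::with_seed(14, { x <- matrix(rnorm(40 * 4), ncol = 4) })
  y <- rep(0:1, 20)
  fm <- feature_matrix(x, sprintf("f%d", 1:4), y)
  fmp <- feature_matrix(x[, 4:1], sprintf("f%d", 4:1), y)
  cfg <- fusion_config(learners = list(stub = hybridbci:::stub_learner()),
                       n_folds = 4, n_repetitions = 1, seed = 2)
  expect_identical(fuse(fm, fm, cfg)$accuracies, fuse(fmp, fmp, cfg)$accuracies)
})

test_that("secondary learning behaves at the oracle and uninformative limits", {
  y_tr <- rep(0:1, each = 20); y_te <- rep(0:1, each = 5)
  # meta-features equal to the labels -> perfect accuracy
  A <- matrix(y_tr, ncol = 1); B <- matrix(y_te, ncol = 1)
  sec <- secondary_learn(A, B, y_tr, y_te)
  expect_equal(sec$accuracy, 1)
  # prediction matches the 1-D separating threshold
  expect_identical(sec$predicted, as.integer(B[, 1] > 0.5))
  # constant meta-features -> majority class
  y_tr2 <- c(rep(0L, 25), rep(1L, 15))
  sec2 <- secondary_learn(matrix(0.5, 40, 1), matrix(0.5, 10, 1),
                          y_tr2, y_te)
  expect_equal(unique(sec2$predicted), 0L)
  expect_equal(sec2$accuracy, mean(y_te == 0L))
})

test_that("fusion is bit-reproducible and exposes tidy summaries", {
  fm_e <- informative_features(n = 60, n_inf = 2, n_noise = 2, seed = 15)
  fm_f <- informative_features(n = 60, n_inf = 2, n_noise = 2, seed = 16)
  cfg <- fusion_config(n_repetitions = 1, n_folds = 4, seed = 9)
  r1 <- fuse(fm_e, fm_f, cfg)
  r2 <- fuse(fm_e, fm_f, cfg)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_s3_class(tidy(r1), "tbl_df")
  expect_equal(nrow(tidy(r1)), 1)
  g <- glance(r1)
  expect_equal(g$n_learners, 4)
  expect_equal(g$accuracy_mean, r1$mean)
  expect_s3_class(autoplot(r1), "ggplot")

  # mismatched labels across modalities refused
  fm_bad <- fm_f; fm_bad$label <- rev(fm_bad$label)
  expect_error(fuse(fm_e, fm_bad, cfg), "paired")
})

test_that("direct splicing concatenates features and tracks redundancy", {
  fm <- informative_features(n = 80, n_inf = 2, n_noise = 2, seed = 17)
  cfg <- fusion_config(n_folds = 4, seed = 3)
  acc_single <- modality_cv_accuracy(fm, n_folds = 4, seed = 3)
  acc_spliced <- direct_splice_baseline(fm, fm, cfg)
  # duplicated informative features add nothing over the single modality
  expect_close(acc_spliced, acc_single, tol = 0.1)
})

test_that("report tables summarise subject-by-condition accuracies", {
  res <- tibble::tibble(
    subject = rep(c("s1", "s2"), each = 2),
    condition = rep(c("fusion", "splice"), 2),
    accuracy = c(0.9, 0.8, 0.7, 0.6)
  )
  rep_tbl <- evaluate_report(res)
  expect_equal(nrow(rep_tbl), 4)
  expect_equal(rep_tbl$fusion[rep_tbl$subject == "mean"], (0.9 + 0.7) / 2)
  expect_equal(rep_tbl$splice[rep_tbl$subject == "sd"], sd(c(0.8, 0.6)))
  # single subject: sd row is zero
  one <- evaluate_report(res[res$subject == "s1", ])
  expect_equal(one$fusion[one$subject == "sd"], 0)
})
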