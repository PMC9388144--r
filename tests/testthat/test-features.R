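test_that("the six statistic features match direct formula evaluation", {
  x <- c(1, 2, 4, 2)
  sub <- subtasks_from_matrices(list(matrix(x, nrow = 1)), fs = 4, labels = 0L)
  fm <- statistic_features(sub)
  v <- as.numeric(feature_values(fm))
  sigma <- sqrt(1.1875)
  expect_close(v, c(2.25, 1.1875, 5 / 3, (5 / 3) / sigma, 1.5, 1.5 / sigma),
               tol = 1e-12)
  expect_identical(feature_names(fm),
                   paste("CH01", c("mean", "var", "diff1", "ndiff1", "diff2", "ndiff2"),
                         sep = "."))

  # constant signal: sigma = 0 convention zeroes the normalised statistics
  subc <- subtasks_from_matrices(list(matrix(7, 1, 5)), fs = 5, labels = 0L)
  expect_equal(as.numeric(feature_values(statistic_features(subc))),
               c(7, 0, 0, 0, 0, 0))

  # dimensional contract: 30 channels -> 180 columns
  withr::with_seed(5, {
    sub30 <- subtasks_from_matrices(list(matrix(rnorm(30 * 10), 30, 10)),
                                    fs = 10, labels = 0L)
  })
  expect_length(feature_names(statistic_features(sub30)), 180)

  expect_error(statistic_features(subtasks_from_matrices(
    list(matrix(1, 1, 2)), fs = 2, labels = 0L)), "3 samples")
})

test_that("differential entropy matches the Gaussian closed form", {
  n <- 1e5; fs <- 200
  withr::with_seed(42, {
    x1 <- rnorm(n, sd = sqrt(1 / (2 * pi * exp(1))))
    x2 <- rnorm(n, sd = 2)
  })
  sub <- subtasks_from_matrices(list(matrix(x1, 1), matrix(x2, 1), matrix(3 * x1, 1)),
                                fs = fs, labels = c(0L, 1L, 0L))
  de <- feature_values(de_feature(sub, band = c(0, fs / 2)))
  # sigma^2 = 1/(2 pi e) makes DE exactly 0
  expect_close(de[1, 1], 0, tol = 0.02)
  # closed form at sigma = 2
  expect_close(de[2, 1], 0.5 * log(2 * pi * exp(1) * 4), tol = 0.02)
  # scaling identity DE(a x) - DE(x) = ln a
  expect_close(de[3, 1] - de[1, 1], log(3), tol = 0.02)
})

test_that("differential entropy clips bands at Nyquist and floors zero variance", {
  sub <- subtasks_from_matrices(list(matrix(rnorm(100), 1)), fs = 10, labels = 0L)
  expect_warning(de_feature(sub, band = c(0.5, 45)), "Nyquist")
  subz <- subtasks_from_matrices(list(matrix(0, 1, 100)), fs = 10, labels = 0L)
  expect_warning(dez <- de_feature(subz, band = c(0.5, 4)), "floored")
  expect_true(is.finite(feature_values(dez)[1, 1]))
})

test_that("periodogram equals the brute-force DFT sum and obeys Parseval", {
  # x = [1,1,1,1]: unpadded P at omega = 0 is |sum x|^2 / N = 4
  pg <- periodogram(c(1, 1, 1, 1))
  expect_equal(pg$power[1], 4)

  brute <- function(x) {
    n <- length(x)
    sapply(0:(n - 1), function(k) {
      w <- 2 * pi * k / n
      Mod(sum(x * exp(-1i * w * (0:(n - 1)))))^2 / n
    })
  }
  withr::with_seed(9, {
    for (n in c(1, 2, 3, 5, 8, 13, 21, 32)) {
      x <- rnorm(n)
      pg <- periodogram(x)
      expect_close(pg$power, brute(x), tol = 1e-9)
      # Parseval on the unpadded grid
      expect_close(sum(pg$power), sum(x^2), tol = 1e-9)
    }
  })
})

test_that("PSD features average the zero-padded periodogram over the band", {
  # all-zero signal -> all-zero features
  subz <- subtasks_from_matrices(list(matrix(0, 2, 10)), fs = 10,
                                 labels = 0L, modality = "nirs_hb")
  expect_equal(max(abs(feature_values(psd_feature(subz)))), 0)

  # hand-computed: mean of P over grid points inside 0.01-0.1 Hz
  withr::with_seed(2, { x <- rnorm(10) })
  sub <- subtasks_from_matrices(list(matrix(x, 1)), fs = 10,
                                labels = 0L, modality = "nirs_hb")
  pg <- periodogram(x, fs = 10, nfft = 1024)
  expected <- mean(pg$power[pg$frequency >= 0.01 & pg$frequency <= 0.1])
  expect_equal(as.numeric(feature_values(psd_feature(sub))), expected)

  # empty band refused
  expect_error(psd_feature(sub, band = c(0.001, 0.002)), "grid")
})

test_that("epoch-scope PSD assigns one spectrum to all subtasks of a trial", {
  withr::with_seed(3, {
    mats <- lapply(1:4, function(i) matrix(rnorm(10), 1, 10))
  })
  sub <- subtasks_from_matrices(mats, fs = 10, labels = rep(0L, 4),
                                modality = "nirs_hb")
  sub$parent_trial <- c(1L, 1L, 2L, 2L)
  sub$subtask_index <- c(0L, 1L, 0L, 1L)
  vals <- feature_values(psd_feature(sub, scope = "epoch"))
  expect_equal(vals[1, ], vals[2, ])
  expect_equal(vals[3, ], vals[4, ])
  expect_false(isTRUE(all.equal(vals[1, ], vals[3, ])))
})

test_that("z-scoring normalises fit rows and never leaks from held-out rows", {
  fm <- feature_matrix(matrix(c(1, 2, 3), ncol = 1), "f1", c(0L, 1L, 0L))
  z <- zscore_apply(fm, zscore_fit(fm))
  expect_close(feature_values(z)[, 1], c(-1.2247449, 0, 1.2247449), tol = 1e-6)

  # constant column maps to zero
  fmc <- feature_matrix(cbind(c(1, 2, 3), c(5, 5, 5)), c("a", "b"), c(0L, 1L, 0L))
  expect_equal(feature_values(zscore_apply(fmc, zscore_fit(fmc)))[, 2], rep(0, 3))

  # model parameters depend only on fit rows
  withr::with_seed(4, {
    fmr <- feature_matrix(matrix(rnorm(40), ncol = 2), c("a", "b"),
                          rep(0:1, 10))
  })
  model <- zscore_fit(fmr, fit_rows = 1:10)
  applied <- zscore_apply(fmr, model)
  fitpart <- feature_values(applied)[1:10, ]
  expect_close(colMeans(fitpart), c(0, 0), tol = 1e-9)
  expect_close(apply(fitpart, 2, function(v) sqrt(mean((v - mean(v))^2))),
               c(1, 1), tol = 1e-9)
  held <- feature_values(applied)[11:20, ]
  expect_gt(max(abs(colMeans(held))), 1e-6)
  expect_error(zscore_fit(fmr, fit_rows = integer(0)), "non-empty")
})

test_that("combining domains concatenates columns without touching rows", {
  withr::with_seed(6, {
    a <- feature_matrix(matrix(rnorm(20), 5), sprintf("t%d", 1:4),
                        rep(0:1, length.out = 5), modality = "eeg", domain = "time")
    b <- feature_matrix(matrix(rnorm(10), 5), sprintf("q%d", 1:2),
                        rep(0:1, length.out = 5), modality = "eeg", domain = "freq")
  })
  ab <- combine_domains(a, b)
  expect_length(feature_names(ab), 6)
  expect_identical(feature_labels(ab), feature_labels(a))
  expect_identical(feature_values(ab), cbind(feature_values(a), feature_values(b)))

  # label mismatch refused
  b2 <- b; b2$label <- c(1L, 0L, 1L, 0L, 1L)
  expect_error(combine_domains(a, b2), "labels")

  # empty right-hand side is the identity
  empty <- feature_matrix(matrix(numeric(0), 0, 0), character(0), integer(0))
  expect_identical(feature_values(combine_domains(a, empty)), feature_values(a))
})

test_that("feature extraction is permutation-equivariant over subtasks", {
  withr::with_seed(8, {
    mats <- lapply(1:6, function(i) matrix(rnorm(3 * 20), 3, 20))
  })
  labels <- rep(0:1, 3)
  sub <- subtasks_from_matrices(mats, fs = 20, labels = labels)
  perm <- c(4, 1, 6, 2, 5, 3)
  subp <- subtasks_from_matrices(mats[perm], fs = 20, labels = labels[perm])
  for (extractor in list(statistic_features,
                         function(s) de_feature(s, band = c(0.5, 9)))) {
    v <- feature_values(extractor(sub))
    vp <- feature_values(extractor(subp))
    expect_equal(vp, v[perm, ])
  }
})
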