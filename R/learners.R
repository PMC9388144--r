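#' Primary learner registry
#'
#' The four primary learners of the progressive-learning stage, each a
#' `fit(x, y, seed)` / `predict_prob(model, x)` pair returning
#' positive-class probabilities:
#' \describe{
#'   \item{`rf`}{100-tree random forest (ranger).}
#'   \item{`xgb`}{depth-wise gradient-boosted trees (xgboost).}
#'   \item{`ada`}{AdaBoost (SAMME) over decision stumps, implemented on
#'     rpart.}
#'   \item{`lgb`}{leaf-wise-grown histogram gradient-boosted trees
#'     (xgboost with `grow_policy = "lossguide"`), the LightGBM-style
#'     growth strategy.}
#' }
#' All learners are deterministic given the seed and run single-threaded.
#'
#' @return named list of learner definitions.
#' @export
learner_registry <- function() {
  list(
    rf = list(
      fit = function(x, y, seed) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                       num.trees = 100, probability = TRUE,
                       seed = seed, num.threads = 1L, verbose = FALSE)
      },
      predict_prob = function(model, x) {
        unname(predict(model, data = x, seed = 1L,
                       num.threads = 1L)$predictions[, "1"])
      }
    ),
    xgb = list(
      fit = function(x, y, seed) {
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 4,
                        eta = 0.3, nthread = 1, seed = seed),
          data = xgboost::xgb.DMatrix(x, label = y), nrounds = 60, verbose = 0
        )
      },
      predict_prob = function(model, x) {
        as.numeric(predict(model, xgboost::xgb.DMatrix(x)))
      }
    ),
    ada = list(
      fit = function(x, y, seed) adaboost_fit(x, y, n_rounds = 50),
      predict_prob = function(model, x) adaboost_prob(model, x)
    ),
    lgb = list(
      fit = function(x, y, seed) {
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", tree_method = "hist",
                        grow_policy = "lossguide", max_leaves = 31,
                        max_depth = 0, eta = 0.1, nthread = 1, seed = seed),
          data = xgboost::xgb.DMatrix(x, label = y), nrounds = 60, verbose = 0
        )
      },
      predict_prob = function(model, x) {
        as.numeric(predict(model, xgboost::xgb.DMatrix(x)))
      }
    )
  )
}

# AdaBoost (discrete SAMME) over depth-1 rpart stumps. Binary labels 0/1.
adaboost_fit <- function(x, y, n_rounds = 50) {
  n <- nrow(x)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- factor(y, levels = c(0, 1))
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != df$.y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    miss <- pred != df$.y
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  structure(list(stumps = stumps, alphas = alphas, n_features = ncol(x)),
            class = "bci_adaboost")
}

adaboost_prob <- function(model, x) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  if (length(model$stumps) == 0) return(rep(0.5, nrow(df)))
  score <- numeric(nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    score <- score + model$alphas[m] * ifelse(pred == "1", 1, -1)
  }
  1 / (1 + exp(-2 * score))
}

# Deterministic stub learner predicting the training-label mean; used by
# tests to audit the stacking bookkeeping by hand.
stub_learner <- function() {
  list(
    fit = function(x, y, seed) list(p = mean(y)),
    predict_prob = function(model, x) rep(model$p, nrow(x))
  )
}
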