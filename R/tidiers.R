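#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fusion result
#'
#' One row per outer-split repetition with its fused test accuracy.
#'
#' @param x a `bci_fusion` object from [fuse()].
#' @param ... unused.
#' @return tibble with columns `repetition`, `accuracy`.
#' @export
tidy.bci_fusion <- function(x, ...) {
  tibble::tibble(repetition = seq_along(x$accuracies), accuracy = x$accuracies)
}

#' Glance at a fusion result
#'
#' @param x a `bci_fusion` object.
#' @param ... unused.
#' @return one-row tibble: mean/sd accuracy, repetitions, learners, folds.
#' @export
glance.bci_fusion <- function(x, ...) {
  tibble::tibble(
    accuracy_mean = x$mean, accuracy_sd = x$sd,
    n_repetitions = length(x$accuracies),
    n_learners = length(x$config$learners),
    n_folds = x$config$n_folds,
    split_ratio = x$config$split_ratio
  )
}

#' Plot per-repetition fusion accuracies
#'
#' @param object a `bci_fusion` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bci_fusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$repetition, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = object$mean, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "repetition (independent 8:2 split)",
                  y = "fused test accuracy",
                  title = sprintf("Progressive-learning fusion: %.3f +/- %.3f",
                                  object$mean, object$sd)) +
    ggplot2::theme_minimal()
}

#' Plot a condition comparison report
#'
#' Bar chart of the per-condition accuracies produced by [run_pipeline()].
#'
#' @param report tibble with `condition` and `accuracy` columns.
#' @return a ggplot.
#' @export
plot_report <- function(report) {
  report$condition <- factor(report$condition, levels = report$condition)
  ggplot2::ggplot(report, ggplot2::aes(x = .data$condition, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the selection fitness trace
#'
#' Best-so-far wrapper fitness per atom-search iteration (non-increasing).
#'
#' @param selection result of [select_features()] (or any list with a
#'   numeric `trace`).
#' @return a ggplot.
#' @export
plot_selection_trace <- function(selection) {
  df <- tibble::tibble(iteration = seq_along(selection$trace),
                       fitness = selection$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best-so-far fitness") +
    ggplot2::theme_minimal()
}
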