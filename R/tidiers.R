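#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an optimizer run into its convergence trace
#'
#' @param x An `optim_result` from [run_ssu_bes()], [run_bes()], or
#'   [run_random_search()].
#' @param ... Unused.
#' @return Tibble: `method`, `iteration`, `best_cost`, `mean_cost`, `evals`.
#' @export
tidy.optim_result <- function(x, ...) {
  dplyr::mutate(x$trace, method = x$method, .before = 1)
}

#' @rdname tidy.optim_result
#' @export
glance.optim_result <- function(x, ...) {
  tibble::tibble(method = x$method, best_cost = x$best_cost, evals = x$evals,
                 iterations = x$config$iters, pop = x$config$pop, dim = x$config$dim)
}

#' Convergence plot of an optimizer run
#'
#' Best (and mean) cost per iteration on a log scale.
#'
#' @param object An `optim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.optim_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("best_cost", "mean_cost"),
                            names_to = "series", values_to = "cost")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$cost,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Iteration", y = "Cost (1 / accuracy)",
                  title = sprintf("Convergence (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Tidy a fitted tri-classifier into long-format metrics
#'
#' @param x A `tri_fit` from [train_tri_classifier()].
#' @param ... Unused.
#' @return Tibble: `metric`, `value` for the 11 validation metrics.
#' @export
tidy.tri_fit <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.tri_fit
#' @export
glance.tri_fit <- function(x, ...) {
  tibble::tibble(optimizer = x$optimizer, accuracy = x$accuracy,
                 f1 = x$metrics$f1, mcc = x$metrics$mcc,
                 n_train = length(x$split$train), n_val = length(x$split$val),
                 best_cost = if (is.null(x$optim)) NA_real_ else x$optim$best_cost,
                 evals = if (is.null(x$optim)) 0L else x$optim$evals)
}

#' Metric profile plot for a fitted tri-classifier
#'
#' @param object A `tri_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of the 11 validation metrics.
#' @export
autoplot.tri_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$metric, .data$value),
                                   y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Value",
                  title = sprintf("Validation metrics (optimizer: %s)", object$optimizer)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
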