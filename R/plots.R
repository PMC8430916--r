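#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic views: the validation-MAE
#' training curve of a network, and the per-phase RI distributions of a
#' simulated corpus. `plot_ri_accuracy()` draws predicted versus reference
#' values with the identity line, the standard accuracy figure of this
#' field.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ristack-plots
NULL

#' @rdname ristack-plots
#' @export
autoplot.ri_net <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$val_mae * 1000)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "training iteration", y = "validation MAE (RI units)",
                  title = sprintf("%s (%s family)", toupper(object$spec$kind),
                                  object$family)) +
    ggplot2::theme_minimal()
}

#' @rdname ristack-plots
#' @export
autoplot.ri_sim_corpus <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$ri, fill = .data$family)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.7, position = "identity") +
    ggplot2::facet_wrap(~family, ncol = 1) +
    ggplot2::labs(x = "retention index", y = "records",
                  title = "Simulated retention corpus") +
    ggplot2::theme_minimal()
}

#' @rdname ristack-plots
#' @param data Tibble of predictions.
#' @param estimate,truth Column names (tidy-eval) of predicted and
#'   reference values.
#' @export
plot_ri_accuracy <- function(data, estimate, truth) {
  est <- rlang::enquo(estimate)
  tru <- rlang::enquo(truth)
  ggplot2::ggplot(data, ggplot2::aes(x = !!tru, y = !!est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.9, color = "steelblue") +
    ggplot2::labs(x = "reference retention index",
                  y = "predicted retention index") +
    ggplot2::theme_minimal()
}
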