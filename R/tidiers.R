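#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for ristack models
#'
#' `tidy()` returns the per-term (or per-checkpoint) view of a fitted
#' object; `glance()` returns a one-row model summary.
#'
#' @param x A fitted ristack object.
#' @param ... Unused.
#' @return A tibble.
#' @name ristack-tidiers
NULL

#' @rdname ristack-tidiers
#' @export
tidy.ri_net <- function(x, ...) x$history

#' @rdname ristack-tidiers
#' @export
glance.ri_net <- function(x, ...) {
  tibble(kind = x$spec$kind, family = x$family,
         n_parameters = param_count(x$best_params),
         iterations = x$protocol$iterations,
         best_iteration = x$best_iteration,
         best_val_mae = if (nrow(x$history)) min(x$history$val_mae) * 1000 else NA_real_)
}

#' @rdname ristack-tidiers
#' @export
tidy.ri_combo_model <- function(x, ...) x$terms

#' @rdname ristack-tidiers
#' @export
glance.ri_combo_model <- function(x, ...) {
  tibble(target = x$target, n_terms = nrow(x$terms),
         coefficient_sum = sum(x$terms$coefficient),
         final_mae = if (!is.null(x$history)) dplyr::last(x$history$mae) else NA_real_)
}

#' @rdname ristack-tidiers
#' @export
tidy.ri_group_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname ristack-tidiers
#' @export
glance.ri_group_model <- function(x, ...) {
  tibble(n = x$n, n_terms = length(x$coefficients) + 1,
         mae = mean(abs(x$residuals)),
         rmse = sqrt(mean(x$residuals^2)))
}

#' @rdname ristack-tidiers
#' @export
glance.ri_stack <- function(x, ...) {
  tibble(kind = x$kind,
         n_support = if (x$kind == "svr") nrow(x$sv) else 0L,
         n_train = x$n_train, n_features = x$n_features,
         epsilon_effective = x$eps_eff, unit = x$unit)
}
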