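#' Hyperparameters of the second-level support-vector model
#'
#' The stacking model is epsilon-insensitive support-vector regression with
#' an exponential (Laplacian) kernel `k(x, y) = exp(-||x - y|| / sigma)`.
#' Defaults are the published working point: `sigma = 31.0`,
#' `epsilon = 0.82`, `C = 31000`, `tolerance = 2.7`. Labels are divided by
#' `label_scale` (1000) for training and predictions are multiplied back.
#'
#' `epsilon_units` states the unit in which `epsilon` and `tolerance` are
#' quoted. With `"index"` (the default) they are read in the same units as
#' the unscaled labels and divided by `label_scale` alongside them, giving
#' an effective tube of 0.00082 on scaled labels; with `"scaled"` they are
#' applied verbatim to the scaled labels, in which case the tube (0.82) is
#' wider than most of the scaled-label range and the fit degenerates
#' towards a flat function. The methods vignette discusses why `"index"` is
#' the default.
#'
#' @param sigma Kernel width (scaled-feature space).
#' @param epsilon Insensitivity-tube half width.
#' @param C Soft-margin box constraint on dual coefficients.
#' @param tolerance Solver convergence tolerance.
#' @param kernel `"laplace"` for `exp(-d/sigma)`, or `"laplace_sigma2"` for
#'   the `exp(-d/(2 sigma^2))` variant.
#' @param epsilon_units `"index"` or `"scaled"` (see Details).
#' @param label_scale Label scaling divisor.
#' @return An `svr_hyperparams` object.
#' @export
svr_hyperparams <- function(sigma = 31.0, epsilon = 0.82, C = 31000,
                            tolerance = 2.7,
                            kernel = c("laplace", "laplace_sigma2"),
                            epsilon_units = c("index", "scaled"),
                            label_scale = 1000) {
  stopifnot(sigma > 0, epsilon >= 0, C > 0, tolerance > 0, label_scale > 0)
  structure(list(sigma = sigma, epsilon = epsilon, C = C,
                 tolerance = tolerance, kernel = match.arg(kernel),
                 epsilon_units = match.arg(epsilon_units),
                 label_scale = label_scale),
            class = "svr_hyperparams")
}

kernlab_kernel <- function(hp) {
  rate <- switch(hp$kernel,
                 laplace = 1 / hp$sigma,
                 laplace_sigma2 = 1 / (2 * hp$sigma^2))
  kernlab::laplacedot(sigma = rate)
}

#' Assemble the 441-feature stacked input
#'
#' Concatenates the 114 predicted-RI features (first, in fixed block order)
#' with the 327 scaled molecular descriptors to form the second-level
#' model's input.
#'
#' @param block 114-column matrix from [ri_feature_block()].
#' @param desc 327-column matrix from [descriptor_matrix()].
#' @return A numeric matrix with 441 named columns; attribute
#'   `manifest_version` records the descriptor manifest.
#' @export
assemble_features <- function(block, desc) {
  block <- rbind(block)
  desc <- rbind(desc)
  if (ncol(block) != 114) abort("predicted-RI block must have 114 columns")
  if (ncol(desc) != 327) abort("descriptor block must have 327 columns")
  if (nrow(block) != nrow(desc)) abort("row mismatch between feature blocks")
  out <- cbind(block, desc)
  attr(out, "manifest_version") <- attr(desc, "manifest_version")
  out
}

#' Train the second-level support-vector stacking model
#'
#' Fits epsilon-SVR on stacked features against retention values divided by
#' `label_scale`. If every scaled target fits inside a single epsilon tube
#' the exact optimum is a bias-only (flat) model, which is returned
#' directly; otherwise the dual problem is solved by a sequential-minimal-
#' optimization solver (kernlab).
#'
#' @param features Matrix from [assemble_features()] (or any fixed-order
#'   numeric feature matrix; the 441-feature layout is the standard use).
#' @param targets Retention indices (or second-dimension retention times;
#'   set `unit`).
#' @param hp An [svr_hyperparams()].
#' @param unit Unit label carried into predictions/reports: `"ri"` (index
#'   units), `"ms"`, or `"s"`.
#' @return An `ri_stack` model object.
#' @export
train_stack <- function(features, targets, hp = svr_hyperparams(),
                        unit = c("ri", "ms", "s")) {
  unit <- match.arg(unit)
  features <- as.matrix(features)
  if (nrow(features) != length(targets)) abort("features/targets length mismatch")
  if (any(!is.finite(features))) abort("features must be finite")
  dup <- duplicated(features) & !duplicated(cbind(features, targets))
  if (any(dup)) {
    warn("identical feature rows with conflicting targets; fit proceeds")
  }
  ys <- targets / hp$label_scale
  eps_eff <- if (hp$epsilon_units == "index") hp$epsilon / hp$label_scale else hp$epsilon
  tol_eff <- if (hp$epsilon_units == "index") hp$tolerance / hp$label_scale else hp$tolerance
  flat <- (max(ys) - min(ys)) <= 2 * eps_eff
  if (flat) {
    model <- list(kind = "bias", b = (max(ys) + min(ys)) / 2)
  } else {
    fit <- tryCatch(
      kernlab::ksvm(features, ys, type = "eps-svr",
                    kernel = kernlab_kernel(hp),
                    C = hp$C, epsilon = eps_eff, tol = tol_eff,
                    scaled = FALSE),
      error = function(e) {
        if (grepl("No Support Vectors", conditionMessage(e))) NULL else
          rlang::cnd_signal(e)
      })
    if (is.null(fit)) {
      model <- list(kind = "bias", b = (max(ys) + min(ys)) / 2)
    } else {
      model <- list(kind = "svr",
                    sv = features[kernlab::SVindex(fit), , drop = FALSE],
                    coef = as.numeric(unlist(kernlab::alpha(fit))),
                    sv_index = kernlab::SVindex(fit),
                    b = kernlab::b(fit))
    }
  }
  structure(c(model,
              list(hp = hp, eps_eff = eps_eff, tol_eff = tol_eff, unit = unit,
                   n_train = length(targets),
                   manifest_version = attr(features, "manifest_version"),
                   n_features = ncol(features))),
            class = "ri_stack")
}

#' Predict with the second-level stacking model
#'
#' Evaluates the kernel expansion (or the flat bias for a degenerate model)
#' and multiplies by `label_scale` to return values in the model's original
#' unit.
#'
#' @param model An `ri_stack`.
#' @param features Feature matrix with the same column layout (and, when
#'   present, the same descriptor-manifest version) as at training.
#' @return Numeric vector of predictions in original units, with a `unit`
#'   attribute.
#' @export
predict_stack <- function(model, features) {
  stopifnot(inherits(model, "ri_stack"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    abort("feature layout does not match the trained model")
  }
  mv <- attr(features, "manifest_version")
  if (!is.null(mv) && !is.null(model$manifest_version) &&
      !identical(mv, model$manifest_version)) {
    abort("descriptor manifest version mismatch between model and features")
  }
  ys <- if (model$kind == "bias") {
    rep(model$b, nrow(features))
  } else {
    K <- kernlab::kernelMatrix(kernlab_kernel(model$hp), features, model$sv)
    drop(K %*% model$coef) - model$b
  }
  out <- ys * model$hp$label_scale
  attr(out, "unit") <- model$unit
  out
}

#' Karush-Kuhn-Tucker diagnostics of a trained stacking model
#'
#' Verifies the epsilon-SVR optimality structure on the training set:
#' every dual coefficient obeys `|alpha| <= C`; points strictly inside the
#' epsilon tube carry zero dual coefficient (they are not support vectors);
#' and bound support vectors (`|alpha| = C`) lie on or outside the tube.
#'
#' @param model An `ri_stack` with `kind = "svr"` (a bias-only model passes
#'   trivially).
#' @param features,targets The training data the model was fitted on.
#' @param slack Numerical slack applied to the comparisons, on the scaled
#'   label axis.
#' @return A list with `ok` (logical) and a `checks` tibble.
#' @export
kkt_check <- function(model, features, targets, slack = 1e-4) {
  stopifnot(inherits(model, "ri_stack"))
  ys <- targets / model$hp$label_scale
  pred <- predict_stack(model, features) / model$hp$label_scale
  r <- pred - ys
  if (model$kind == "bias") {
    checks <- tibble(check = "bias-only model: all residuals inside tube",
                     ok = all(abs(r) <= model$eps_eff + slack))
    return(list(ok = all(checks$ok), checks = checks))
  }
  C <- model$hp$C
  slack <- max(slack, model$tol_eff %||% 0)
  alpha <- numeric(length(ys))
  alpha[model$sv_index] <- model$coef
  inside <- abs(r) < model$eps_eff - slack
  bound <- abs(abs(alpha) - C) <= C * 1e-6
  free_sv <- alpha != 0 & !bound
  checks <- tibble(
    check = c("dual coefficients bounded by C",
              "points strictly inside the tube have zero dual coefficient",
              "free support vectors lie on the tube boundary",
              "bound support vectors lie on or outside the tube"),
    ok = c(all(abs(alpha) <= C * (1 + 1e-6)),
           all(alpha[inside] == 0),
           all(abs(abs(r[free_sv]) - model$eps_eff) <= slack * 10 + 1e-6),
           all(abs(r[bound]) >= model$eps_eff - slack))
  )
  list(ok = all(checks$ok), checks = checks)
}

#' @export
print.ri_stack <- function(x, ...) {
  if (x$kind == "bias") {
    cat(sprintf("<ri_stack bias-only> b = %.4f (x%g %s)\n",
                x$b, x$hp$label_scale, x$unit))
  } else {
    cat(sprintf("<ri_stack> %d support vectors / %d points, %d features, unit %s\n",
                nrow(x$sv), x$n_train, x$n_features, x$unit))
  }
  invisible(x)
}
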