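#' Linear functional-group-contribution baseline
#'
#' Fits the classical linear retention model: RI is an intercept plus one
#' additive contribution per functional-group counter, estimated by ordinary
#' least squares on the full data set (no train/test split is used for this
#' baseline; a model linear in 84 counters is robust to overfitting at
#' corpus scale). A rank-deficient design falls back to the minimum-norm
#' least-squares solution with a warning.
#'
#' @param records Tibble with `smiles` and `ri` columns (one phase or phase
#'   family at a time).
#' @param counts Optional precomputed counter matrix from
#'   [functional_group_counts()]; computed from `records$smiles` if missing.
#' @return An object of class `ri_group_model` with `intercept`,
#'   `coefficients` (named, RI units per group occurrence), `fitted` and
#'   `residuals`.
#' @export
fit_group_contributions <- function(records, counts = NULL) {
  assert_cols(records, c("smiles", "ri"))
  if (is.null(counts)) counts <- functional_group_counts(records$smiles)
  stopifnot(nrow(counts) == nrow(records))
  y <- records$ri
  X <- cbind(`(Intercept)` = 1, counts)
  if (nrow(X) < ncol(X)) {
    warn("fewer records than parameters: coefficients are not identifiable")
  }
  qr_fit <- qr(X)
  if (qr_fit$rank < ncol(X)) {
    warn("rank-deficient counter design: using minimum-norm least squares")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qr_fit, y)
  }
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  structure(list(intercept = beta[[1]],
                 coefficients = beta[-1],
                 fitted = fitted,
                 residuals = y - fitted,
                 n = length(y)),
            class = "ri_group_model")
}

#' @export
predict.ri_group_model <- function(object, smiles = NULL, counts = NULL, ...) {
  if (is.null(counts)) {
    if (is.null(smiles)) abort("provide smiles or a counter matrix")
    counts <- functional_group_counts(smiles)
  }
  drop(object$intercept + counts %*% object$coefficients)
}

#' @export
print.ri_group_model <- function(x, ...) {
  cat(sprintf("<ri_group_model> intercept %.1f, %d group coefficients, n = %d\n",
              x$intercept, length(x$coefficients), x$n))
  invisible(x)
}

new_ri_combo <- function(terms, history = NULL, target = NA_character_) {
  stopifnot(is.data.frame(terms), all(c("phase", "coefficient") %in% names(terms)))
  if (nrow(terms) > 5) abort("a phase-combination model has at most five terms")
  if (any(!is.finite(terms$coefficient))) abort("coefficients must be finite")
  structure(list(terms = as_tibble(terms), history = history, target = target),
            class = "ri_combo_model")
}

#' Greedy few-parameter phase-combination models
#'
#' Builds an intercept-free linear model expressing the retention index on a
#' data-poor target phase as a combination of RI values on well-covered
#' phases. The first phase entered is the one whose RI values correlate most
#' with the target (largest absolute Pearson correlation); each subsequent
#' step adds the candidate phase yielding the largest MAE gain, refitting
#' all coefficients by least squares, and stops when the gain drops below
#' `gain_threshold` MAE units or five terms are reached. The solvation-model
#' rationale: if log k obeys a five-parameter linear solvation equation,
#' log k (and hence RI, which is affine in log k under an isothermal alkane
#' ladder) on any liquid phase is a combination of at most five others.
#'
#' @param candidates Data frame or matrix of candidate-phase RI values, one
#'   column per phase, rows aligned with `target`.
#' @param target Numeric vector of RI values on the target phase.
#' @param gain_threshold Minimum MAE improvement (index units) to accept a
#'   further term; the customary range is 3-5.
#' @param max_terms Hard cap on the number of terms (5).
#' @param exclude Optional character matrix / data frame of phase-name pairs
#'   that must not enter the model together (phases of near-identical
#'   polarity); off by default.
#' @return An `ri_combo_model` with a `terms` tibble (`phase`,
#'   `coefficient`) and a per-step `history`.
#' @export
greedy_sp_combination <- function(candidates, target, gain_threshold = 4,
                                  max_terms = 5, exclude = NULL) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X)) || ncol(X) == 0) {
    abort("candidates must be a named, non-empty set of phase RI columns")
  }
  stopifnot(nrow(X) == length(target))
  fit_mae <- function(cols) {
    b <- qr.coef(qr(X[, cols, drop = FALSE]), target)
    b[is.na(b)] <- 0
    list(coef = b, mae = mean(abs(target - X[, cols, drop = FALSE] %*% b)))
  }
  blocked <- function(cand, chosen) {
    if (is.null(exclude) || length(chosen) == 0) return(FALSE)
    ex <- as.matrix(exclude)
    any(apply(ex, 1, function(p) {
      (p[1] == cand && p[2] %in% chosen) || (p[2] == cand && p[1] %in% chosen)
    }))
  }
  cors <- abs(suppressWarnings(stats::cor(X, target)))
  cors[!is.finite(cors)] <- -Inf
  chosen <- colnames(X)[which.max(cors)]
  cur <- fit_mae(chosen)
  history <- tibble(step = 1L, phase = chosen, mae = cur$mae, gain = NA_real_)
  repeat {
    if (length(chosen) >= min(max_terms, 5L)) break
    rest <- setdiff(colnames(X), chosen)
    rest <- rest[!vapply(rest, blocked, logical(1), chosen = chosen)]
    if (length(rest) == 0) break
    trials <- lapply(rest, function(p) fit_mae(c(chosen, p)))
    maes <- vapply(trials, `[[`, numeric(1), "mae")
    best <- which.min(maes)  # ties: first (lowest registry index) wins
    gain <- cur$mae - maes[best]
    if (gain < gain_threshold) break
    chosen <- c(chosen, rest[best])
    cur <- trials[[best]]
    history <- dplyr::bind_rows(history,
      tibble(step = length(chosen), phase = rest[best],
             mae = cur$mae, gain = gain))
  }
  new_ri_combo(tibble(phase = chosen, coefficient = unname(cur$coef)),
               history = history)
}

#' Apply a phase-combination model
#'
#' Evaluates the intercept-free dot product of a combination model's
#' coefficients with RI values on its input phases.
#'
#' @param model An `ri_combo_model`.
#' @param ri_inputs A named numeric vector, a one-row named list, or a data
#'   frame with one column per input phase (multiple rows give a vector of
#'   predictions). All phases of the model must be present.
#' @return Numeric vector of predicted RI on the target phase.
#' @export
#' @examples
#' eqs <- builtin_combo_equations()
#' apply_combo(eqs[["DB-1701"]], c("DB-624" = 1000, "DB-WAX" = 1000))
apply_combo <- function(model, ri_inputs) {
  stopifnot(inherits(model, "ri_combo_model"))
  if (is.data.frame(ri_inputs)) {
    miss <- setdiff(model$terms$phase, names(ri_inputs))
    if (length(miss)) abort(paste("missing input phase(s):",
                                  paste(miss, collapse = ", ")))
    M <- as.matrix(ri_inputs[, model$terms$phase, drop = FALSE])
    return(drop(M %*% model$terms$coefficient))
  }
  v <- unlist(ri_inputs)
  miss <- setdiff(model$terms$phase, names(v))
  if (length(miss)) abort(paste("missing input phase(s):",
                                paste(miss, collapse = ", ")))
  sum(v[model$terms$phase] * model$terms$coefficient)
}

#' Built-in phase-combination equations for DB-1701 and DB-210
#'
#' The two fixed combination models shipped with the package: DB-1701
#' (14% cyanopropylphenyl / 86% dimethyl polysiloxane) from DB-624 and
#' DB-WAX, and DB-210 (50% trifluoropropylmethyl polysiloxane) from five
#' phases. Coefficients are stored exactly as published for these columns.
#'
#' @return A named list of two `ri_combo_model` objects.
#' @export
#' @examples
#' vapply(builtin_combo_equations(), function(m) nrow(m$terms), integer(1))
builtin_combo_equations <- function() {
  list(
    "DB-1701" = new_ri_combo(
      tibble(phase = c("DB-624", "DB-WAX"),
             coefficient = c(0.949, 0.0769)),
      target = "DB-1701"),
    "DB-210" = new_ri_combo(
      tibble(phase = c("Squalane", "DB-1", "DB-5", "DB-624", "DB-WAX"),
             coefficient = c(-3.3267, -0.3007, 3.0737, 1.72, -0.1071)),
      target = "DB-210")
  )
}

#' @export
print.ri_combo_model <- function(x, ...) {
  cat(sprintf("<ri_combo_model>%s %d term(s):\n",
              if (is.na(x$target)) "" else paste0(" target ", x$target),
              nrow(x$terms)))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  %+.4f x RI[%s]\n", x$terms$coefficient[i], x$terms$phase[i]))
  }
  invisible(x)
}
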