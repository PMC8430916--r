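#' Neural base-model specifications
#'
#' Describes one of the two base regressor architectures. The MLP consumes
#' the 327-descriptor vector concatenated with the 38-slot phase encoding
#' (365 inputs) through a stack of residual dense blocks. The CNN consumes
#' the tokenized canonical SMILES through an embedding and two
#' convolutional layers with max pooling, merges the phase encoding after
#' global pooling, and finishes with a dense head. Both end in a single
#' linear output trained against RI/1000.
#'
#' @param kind `"mlp"` or `"cnn"`.
#' @param hidden MLP hidden width.
#' @param blocks Number of MLP residual blocks.
#' @param embed CNN token-embedding dimension.
#' @param channels CNN channel counts for the two convolutional layers.
#' @param kernel CNN kernel width (odd).
#' @param dense CNN dense-head width.
#' @param L_max Maximum tokenized-SMILES length (even).
#' @param alphabet SMILES token alphabet.
#' @return A `net_spec` object.
#' @export
net_spec <- function(kind = c("mlp", "cnn"), hidden = 512, blocks = 3,
                     embed = 16, channels = c(32, 64), kernel = 5,
                     dense = 128, L_max = 150, alphabet = smiles_alphabet()) {
  kind <- match.arg(kind)
  if (kind == "cnn") {
    stopifnot(kernel %% 2 == 1, length(channels) == 2)
    if (L_max %% 2 != 0) L_max <- L_max + 1
  }
  structure(list(kind = kind, hidden = hidden, blocks = blocks, embed = embed,
                 channels = channels, kernel = kernel, dense = dense,
                 L_max = as.integer(L_max), alphabet = alphabet),
            class = "net_spec")
}

#' Training protocol for the neural base models
#'
#' Bundles the optimization settings: mini-batch size 256; 50,000 iterations
#' for base (non-polar) training and 10,000 for the transfer stage; 10% of
#' the training *compounds* isolated before training as a validation set
#' used for early stopping (the parameters from the checkpoint with the best
#' validation MAE are the ones used for prediction).
#'
#' @param iterations Number of mini-batch updates.
#' @param batch_size Mini-batch size.
#' @param validation_fraction Fraction of training compounds held out for
#'   validation/early stopping.
#' @param checkpoint_every Validation cadence in iterations.
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling initialization, the validation
#'   split and batch order.
#' @param stage `"base"` or `"transfer"`; sets the default iteration budget.
#' @return A `train_protocol` object.
#' @export
train_protocol <- function(iterations = NULL, batch_size = 256,
                           validation_fraction = 0.10,
                           checkpoint_every = 500, lr = 1e-3, seed = 1,
                           stage = c("base", "transfer")) {
  stage <- match.arg(stage)
  iterations <- iterations %||% if (stage == "base") 50000L else 10000L
  stopifnot(iterations >= 0, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 checkpoint_every = as.integer(checkpoint_every),
                 lr = lr, seed = as.integer(seed), stage = stage),
            class = "train_protocol")
}

# Featurize records for a given spec/family: returns the data list consumed
# by the engine plus per-record compound keys and scaled targets.
prepare_net_data <- function(records, spec, family, registry, manifest) {
  assert_cols(records, c("smiles", "phase", "ri"))
  parsed <- parse_molecules(records$smiles)
  if (any(!parsed$valid)) abort("records contain unparseable SMILES; run admit_records() first")
  can <- parsed$canonical_smiles
  ucan <- unique(can)
  mi <- match(can, ucan)
  SP <- sp_encode(records$phase, family, registry)
  data <- list(SP = SP)
  if (spec$kind == "mlp") {
    D <- descriptor_matrix(ucan, manifest)
    data$X <- cbind(D[mi, , drop = FALSE], SP)
  } else {
    toks <- tokenize_smiles(ucan, spec$alphabet)
    over <- lengths(toks) > spec$L_max
    if (any(over)) {
      abort(sprintf("%d molecule(s) exceed the CNN L_max of %d tokens",
                    sum(over), spec$L_max))
    }
    idxu <- matrix(0L, length(ucan), spec$L_max)
    for (i in seq_along(toks)) idxu[i, seq_along(toks[[i]])] <- toks[[i]]
    data$idx <- idxu[mi, , drop = FALSE]
  }
  list(data = data, keys = parsed$compound_key, y = records$ri / 1000)
}

new_ri_net <- function(spec, family, fit, protocol, registry, manifest) {
  structure(list(spec = spec, family = family,
                 final_params = fit$final_params,
                 best_params = fit$best_params,
                 best_iteration = fit$best_iteration,
                 history = fit$history,
                 protocol = protocol,
                 registry_version = registry$version,
                 manifest_version = attr(manifest, "version")),
            class = "ri_net")
}

#' Train a base retention-index network on non-polar records
#'
#' Trains the MLP or CNN base model on retention records for non-polar
#' stationary phases. Targets are scaled by 1/1000; the loss is mean
#' absolute error; 10% of the compounds are isolated for validation before
#' training and the checkpoint with the best validation MAE supplies
#' `best_params` (used for prediction), while `final_params` (after the
#' last iteration) are kept as the initialization for transfer learning.
#'
#' @param records Admitted record tibble (`smiles`, `phase`, `ri`; family
#'   must match `family`).
#' @param spec A [net_spec()].
#' @param protocol A [train_protocol()].
#' @param family Phase family of the records/encoding.
#' @param registry Phase registry.
#' @param manifest Descriptor manifest (MLP only).
#' @param init Optional initial parameters (used by [transfer_train()]).
#' @return An `ri_net` object.
#' @export
train_base <- function(records, spec = net_spec("mlp"),
                       protocol = train_protocol(stage = "base"),
                       family = "non-polar",
                       registry = default_phase_registry(),
                       manifest = default_descriptor_manifest(),
                       init = NULL) {
  prep <- prepare_net_data(records, spec, family, registry, manifest)
  keys <- unique(prep$keys)
  n_val <- max(1L, round(protocol$validation_fraction * length(keys)))
  if (length(keys) < 2) abort("need at least two compounds to split off validation")
  val_keys <- with_seed_(derive_seed(protocol$seed, "valsplit"),
                         sample(keys, n_val))
  val_rows <- which(prep$keys %in% val_keys)
  train_rows <- setdiff(seq_along(prep$keys), val_rows)
  if (length(train_rows) == 0 || length(val_rows) == 0) {
    abort("training or validation partition is empty")
  }
  params <- init %||% init_params_for(spec, registry,
                                      derive_seed(protocol$seed, "init"))
  check_param_shapes(params, spec, registry)
  fit <- train_loop(spec$kind, params, prep$data, prep$y, train_rows, val_rows,
                    protocol$iterations, protocol$batch_size,
                    protocol$checkpoint_every, protocol$lr, protocol$seed)
  net <- new_ri_net(spec, family, fit, protocol, registry, manifest)
  net$n_train_records <- length(train_rows)
  net$n_val_records <- length(val_rows)
  net
}

init_params_for <- function(spec, registry, seed) {
  if (spec$kind == "mlp") {
    init_mlp_params(327 + registry$encoding_length, spec$hidden, spec$blocks, seed)
  } else {
    init_cnn_params(length(spec$alphabet), spec$embed, spec$channels,
                    spec$kernel, spec$dense, registry$encoding_length, seed)
  }
}

check_param_shapes <- function(params, spec, registry) {
  ref <- init_params_for(spec, registry, 1L)
  same <- function(a, b) {
    if (is.list(a) != is.list(b)) return(FALSE)
    if (is.list(a)) {
      length(a) == length(b) &&
        all(mapply(same, a, b))
    } else identical(dim(a) %||% length(a), dim(b) %||% length(b))
  }
  if (!same(params, ref)) {
    abort("initial parameters are not shape-compatible with this network spec")
  }
  invisible(TRUE)
}

#' Transfer-train a polar-phase network from a non-polar base network
#'
#' Initializes a polar-phase model with the weights and biases of a base
#' network after its final training iteration (`final_params`), then
#' continues training on polar-phase records under a shorter schedule
#' (default 10,000 iterations) with the same best-validation checkpointing.
#' The shared 38-slot phase encoding keeps the architecture identical, so
#' the initialization is a pure weight copy.
#'
#' @param base_net A trained `ri_net` (non-polar).
#' @param records Polar-phase record tibble.
#' @param protocol A [train_protocol()]; defaults to the transfer stage.
#' @inheritParams train_base
#' @return An `ri_net` for the polar family.
#' @export
transfer_train <- function(base_net, records,
                           protocol = train_protocol(stage = "transfer"),
                           registry = default_phase_registry(),
                           manifest = default_descriptor_manifest()) {
  stopifnot(inherits(base_net, "ri_net"))
  if (protocol$iterations == 0) {
    # no-op schedule: the transferred weights are returned unchanged
    fit <- list(final_params = base_net$final_params,
                best_params = base_net$final_params,
                best_iteration = 0L,
                history = tibble(iteration = integer(), val_mae = numeric()))
    net <- new_ri_net(base_net$spec, "polar", fit, protocol, registry, manifest)
    return(net)
  }
  train_base(records, spec = base_net$spec, protocol = protocol,
             family = "polar", registry = registry, manifest = manifest,
             init = base_net$final_params)
}

#' Predict retention indices with a trained network
#'
#' Runs the best-validation parameters of a trained network on molecules
#' and phases and rescales the output to index units (network output times
#' 1000).
#'
#' @param net A trained `ri_net`.
#' @param smiles Character vector of SMILES.
#' @param phase Phase name(s), recycled against `smiles`.
#' @param registry Phase registry (must match the net's family usage).
#' @param manifest Descriptor manifest.
#' @param params Which parameter set to use, `"best"` (default) or `"final"`.
#' @return A tibble `smiles`, `phase`, `ri_pred`.
#' @export
predict_ri <- function(net, smiles, phase,
                       registry = default_phase_registry(),
                       manifest = default_descriptor_manifest(),
                       params = c("best", "final")) {
  stopifnot(inherits(net, "ri_net"))
  params <- match.arg(params)
  nml <- max(length(smiles), length(phase))
  smiles <- rep_len(smiles, nml)
  phase <- rep_len(phase, nml)
  prep <- prepare_net_data(tibble(smiles = smiles, phase = phase, ri = 0),
                           net$spec, net$family, registry, manifest)
  p <- if (params == "best") net$best_params else net$final_params
  pred <- net_predict_scaled(net$spec$kind, p, prep$data)
  tibble(smiles = smiles, phase = phase, ri_pred = pred * 1000)
}

#' Ensemble average of model predictions
#'
#' The simple arithmetic mean of two or more aligned prediction vectors for
#' the same (molecule, phase) pairs; averaging the CNN and MLP outputs is
#' the package's strongest single-number prediction for polar phases.
#'
#' @param ... Numeric vectors of equal length (at least one).
#' @return Element-wise mean.
#' @export
#' @examples
#' ensemble_average(c(1000, 1200), c(1100, 1300))
ensemble_average <- function(...) {
  preds <- list(...)
  if (length(preds) == 1 && is.list(preds[[1]])) preds <- preds[[1]]
  if (length(preds) == 0) abort("at least one prediction vector is required")
  if (length(preds) == 1) return(mean(preds[[1]]))
  rowMeans(do.call(cbind, preds))
}

#' Predicted-RI feature block for the second-level model
#'
#' For each molecule, predicts RI on every registry phase with all four
#' base networks: 36 non-polar phases for each of CNN and MLP, 21 polar
#' phases for each of CNNPolar and MLPPolar, giving 2x36 + 2x21 = 114
#' features per compound, all divided by 1000. Column order is fixed by the
#' registry and network roles and is stable across calls.
#'
#' @param nets Named list with elements `cnn`, `mlp`, `cnn_polar`,
#'   `mlp_polar`, each a trained `ri_net` (the non-polar/polar roles must
#'   match their families).
#' @param smiles Character vector of molecules.
#' @param registry Phase registry.
#' @param manifest Descriptor manifest.
#' @return Numeric matrix, one row per molecule, 114 named columns
#'   (`<net>|<phase>`), values in RI/1000 units.
#' @export
ri_feature_block <- function(nets, smiles,
                             registry = default_phase_registry(),
                             manifest = default_descriptor_manifest()) {
  need <- c("cnn", "mlp", "cnn_polar", "mlp_polar")
  miss <- setdiff(need, names(nets))
  if (length(miss)) {
    abort(paste("incomplete ensemble, missing net(s):", paste(miss, collapse = ", ")))
  }
  fam <- c(cnn = "non-polar", mlp = "non-polar",
           cnn_polar = "polar", mlp_polar = "polar")
  cols <- list()
  for (nm in need) {
    net <- nets[[nm]]
    stopifnot(inherits(net, "ri_net"))
    if (net$family != fam[[nm]]) {
      abort(sprintf("net '%s' must be a %s-family model", nm, fam[[nm]]))
    }
    phases <- if (fam[[nm]] == "non-polar") registry$nonpolar_types else
      registry$polar_types
    prep <- prepare_net_data(tibble(smiles = smiles, phase = phases[1], ri = 0),
                             net$spec, net$family, registry, manifest)
    block <- matrix(NA_real_, length(smiles), length(phases),
                    dimnames = list(NULL, paste0(nm, "|", phases)))
    for (j in seq_along(phases)) {
      prep$data$SP <- sp_encode(rep(phases[j], length(smiles)), fam[[nm]],
                                registry)
      if (net$spec$kind == "mlp") {
        prep$data$X[, 328:ncol(prep$data$X)] <- prep$data$SP
      }
      block[, j] <- net_predict_scaled(net$spec$kind, net$best_params, prep$data)
    }
    cols[[nm]] <- block
  }
  out <- do.call(cbind, cols[need])
  stopifnot(ncol(out) == 114)
  out
}

#' @export
print.ri_net <- function(x, ...) {
  cat(sprintf("<ri_net %s | %s> %s params, best val MAE %.1f RI units @ iter %d\n",
              toupper(x$spec$kind), x$family,
              format(param_count(x$best_params), big.mark = ","),
              if (nrow(x$history)) min(x$history$val_mae) * 1000 else NA,
              x$best_iteration))
  invisible(x)
}
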