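#' Fit the full set of base and transfer networks on a retention corpus
#'
#' Desk-scale end-to-end training: the MLP and CNN base models are trained
#' on the non-polar records, then the polar models (MLPPolar, CNNPolar) are
#' derived from them by transfer learning on the polar records. Default
#' architecture and iteration budgets are the package's desk-scale
#' configuration (documented in the methods vignette); pass explicit specs
#' and protocols for larger corpora.
#'
#' @param records Admitted record tibble with `smiles`, `phase`, `family`,
#'   `ri`; must contain both non-polar and polar records.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param mlp_spec,cnn_spec Network specifications.
#' @param base_protocol,transfer_protocol Training protocols; defaults use
#'   5,000 base and 2,000 transfer iterations with checkpointing every 500.
#' @param registry Phase registry.
#' @param manifest Descriptor manifest.
#' @return An `ri_model_set`: list of four trained nets (`mlp`, `cnn`,
#'   `mlp_polar`, `cnn_polar`).
#' @export
fit_ri_models <- function(records, seed = 1,
                          mlp_spec = net_spec("mlp", hidden = 160, blocks = 3),
                          cnn_spec = net_spec("cnn", embed = 8,
                                              channels = c(12, 24),
                                              dense = 48, L_max = 44),
                          base_protocol = train_protocol(iterations = 5000,
                                                         stage = "base",
                                                         seed = derive_seed(seed, "base")),
                          transfer_protocol = train_protocol(iterations = 2000,
                                                             stage = "transfer",
                                                             seed = derive_seed(seed, "transfer")),
                          registry = default_phase_registry(),
                          manifest = default_descriptor_manifest()) {
  assert_cols(records, c("smiles", "phase", "family", "ri"))
  np <- dplyr::filter(records, .data$family == "non-polar")
  po <- dplyr::filter(records, .data$family == "polar")
  if (nrow(np) == 0 || nrow(po) == 0) {
    abort("records must include both non-polar and polar families")
  }
  mlp <- train_base(np, mlp_spec, base_protocol, registry = registry,
                    manifest = manifest)
  cnn <- train_base(np, cnn_spec, base_protocol, registry = registry,
                    manifest = manifest)
  mlp_polar <- transfer_train(mlp, po, transfer_protocol,
                              registry = registry, manifest = manifest)
  cnn_polar <- transfer_train(cnn, po, transfer_protocol,
                              registry = registry, manifest = manifest)
  structure(list(nets = list(mlp = mlp, cnn = cnn,
                             mlp_polar = mlp_polar, cnn_polar = cnn_polar),
                 registry_version = registry$version,
                 manifest_version = attr(manifest, "version"),
                 seed = seed),
            class = "ri_model_set")
}

#' @export
print.ri_model_set <- function(x, ...) {
  cat("<ri_model_set> four nets (mlp, cnn, mlp_polar, cnn_polar)\n")
  for (nm in names(x$nets)) {
    cat(sprintf("  %-10s best val MAE %.1f RI units\n", nm,
                min(x$nets[[nm]]$history$val_mae, na.rm = TRUE) * 1000))
  }
  invisible(x)
}

#' Ensemble retention-index predictions from a model set
#'
#' Predicts RI for molecules on a registry phase with the two nets of the
#' matching family and their ensemble average.
#'
#' @param models An `ri_model_set` from [fit_ri_models()].
#' @param smiles Molecules.
#' @param phase Phase name (registry phase of the given family).
#' @param family `"non-polar"` or `"polar"`.
#' @param registry,manifest Registry and manifest used at training.
#' @return A tibble `smiles`, `phase`, `ri_mlp`, `ri_cnn`, `ri_ensemble`.
#' @export
predict_ri_models <- function(models, smiles, phase, family = "polar",
                              registry = default_phase_registry(),
                              manifest = default_descriptor_manifest()) {
  stopifnot(inherits(models, "ri_model_set"))
  pair <- if (family == "polar") {
    list(mlp = models$nets$mlp_polar, cnn = models$nets$cnn_polar)
  } else {
    list(mlp = models$nets$mlp, cnn = models$nets$cnn)
  }
  pm <- predict_ri(pair$mlp, smiles, phase, registry, manifest)
  pc <- predict_ri(pair$cnn, smiles, phase, registry, manifest)
  tibble(smiles = pm$smiles, phase = pm$phase,
         ri_mlp = pm$ri_pred, ri_cnn = pc$ri_pred,
         ri_ensemble = ensemble_average(pm$ri_pred, pc$ri_pred))
}

#' Stacked 441-feature matrix for second-level models
#'
#' Convenience assembly of the full stacked input for a set of molecules:
#' the 114 predicted-RI features from the four nets followed by the 327
#' scaled descriptors.
#'
#' @inheritParams predict_ri_models
#' @return A 441-column feature matrix (see [assemble_features()]).
#' @export
stack_features <- function(models, smiles,
                           registry = default_phase_registry(),
                           manifest = default_descriptor_manifest()) {
  stopifnot(inherits(models, "ri_model_set"))
  block <- ri_feature_block(models$nets, smiles, registry, manifest)
  desc <- descriptor_matrix(parse_molecules(smiles)$canonical_smiles, manifest)
  assemble_features(block, desc)
}
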