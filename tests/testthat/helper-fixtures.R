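# Shared fixtures, computed once per test run and cached in a local env.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# small simulated corpus for unit tests (150 analytes, default phases)
tiny_corpus <- function() {
  fixture("tiny_corpus", {
    lib <- generate_library(150, seed = 401)
    build_corpus(lib, sim_default_phases(), seed = 402)
  })
}

tiny_records <- function() {
  fixture("tiny_records", admit_records(tiny_corpus()$records))
}

# a fast MLP trained for a few hundred iterations on the tiny corpus
tiny_mlp <- function() {
  fixture("tiny_mlp", {
    np <- dplyr::filter(tiny_records(), family == "non-polar")
    train_base(np, net_spec("mlp", hidden = 48, blocks = 1),
               train_protocol(iterations = 400, checkpoint_every = 100,
                              seed = 11, stage = "base"))
  })
}

# an ri_net that outputs a constant scaled value for any input
constant_net <- function(kind = "mlp", value = 1.0, family = "non-polar") {
  spec <- if (kind == "mlp") net_spec("mlp", hidden = 8, blocks = 1) else
    net_spec("cnn", embed = 4, channels = c(3, 5), dense = 6, L_max = 44)
  reg <- default_phase_registry()
  params <- ristack:::init_params_for(spec, reg, 1L)
  zero <- ristack:::param_zeros(params)
  zero$bout <- value
  fit <- list(final_params = zero, best_params = zero, best_iteration = 0L,
              history = tibble::tibble(iteration = integer(),
                                       val_mae = numeric()))
  ristack:::new_ri_net(spec, family, fit,
                       train_protocol(iterations = 0, seed = 1),
                       reg, default_descriptor_manifest())
}

# exhaustive least-squares oracle over all candidate subsets up to max_terms
brute_force_combo <- function(X, y, max_terms = 2) {
  best <- NULL
  cols <- colnames(X)
  for (k in 1:max_terms) {
    for (sub in utils::combn(cols, k, simplify = FALSE)) {
      b <- qr.coef(qr(X[, sub, drop = FALSE]), y)
      mae <- mean(abs(y - X[, sub, drop = FALSE] %*% b))
      if (is.null(best) || mae < best$mae) {
        best <- list(cols = sub, coef = b, mae = mae)
      }
    }
  }
  best
}
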