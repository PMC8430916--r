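# Minimal dense/convolutional network engine on base-R matrix algebra.
# Two fixed architectures are implemented: a residual MLP over descriptor +
# phase-encoding inputs and a character-level 1D CNN over tokenized SMILES
# with the phase encoding merged before the dense head. Training is Adam on
# mean-absolute-error loss of /1000-scaled retention indices.

# Z is always a freshly allocated matmul result here, so the in-place
# compiled kernels are safe.
bias_relu_ <- function(Z, b) {
  add_bias_relu_cpp(Z, b)
  Z
}

# ---- parameter containers -------------------------------------------------

init_mlp_params <- function(d_in, hidden, blocks, seed) {
  with_seed_(seed, {
    he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
    p <- list(W0 = he(d_in, hidden), b0 = numeric(hidden), blocks = list(),
              Wout = he(hidden, 1) / 10, bout = 0)
    for (k in seq_len(blocks)) {
      p$blocks[[k]] <- list(W1 = he(hidden, hidden), b1 = numeric(hidden),
                            W2 = he(hidden, hidden) / blocks, b2 = numeric(hidden))
    }
    p
  })
}

init_cnn_params <- function(n_alpha, embed, channels, kernel, dense, d_sp, seed) {
  with_seed_(seed, {
    he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
    list(E = he(n_alpha, embed),
         Wc1 = he(kernel * embed, channels[1]), bc1 = numeric(channels[1]),
         Wc2 = he(kernel * channels[1], channels[2]), bc2 = numeric(channels[2]),
         Wd = he(2 * channels[2] + d_sp, dense), bd = numeric(dense),
         Wout = he(dense, 1) / 10, bout = 0)
  })
}

param_count <- function(p) {
  if (is.list(p)) sum(vapply(p, param_count, numeric(1))) else length(p)
}

# Adam state mirrors the nested parameter structure; updates run in place
# through the compiled kernel, leaf by leaf. The training loop owns private
# copies of params/m/v, so in-place mutation never leaks.
param_zeros <- function(p) {
  if (is.list(p)) lapply(p, param_zeros) else p * 0
}

param_copy <- function(p) {
  if (is.list(p)) lapply(p, param_copy) else p + 0
}

adam_new <- function(params) {
  list(m = param_zeros(params), v = param_zeros(params), t = 0)
}

adam_update_nested <- function(params, grads, m, v, t, lr) {
  if (is.list(params)) {
    for (k in seq_along(params)) {
      adam_update_nested(params[[k]], grads[[k]], m[[k]], v[[k]], t, lr)
    }
  } else {
    adam_update_cpp(params, m, v, grads, lr, t, 0.9, 0.999, 1e-8)
  }
  invisible(NULL)
}

# ---- residual MLP ---------------------------------------------------------

mlp_forward <- function(p, X, keep_cache = FALSE) {
  A0 <- bias_relu_(X %*% p$W0, p$b0)
  cache <- if (keep_cache) list(X = X, A0 = A0, blocks = list()) else NULL
  h <- A0
  for (k in seq_along(p$blocks)) {
    bk <- p$blocks[[k]]
    U <- bias_relu_(h %*% bk$W1, bk$b1)
    hnew <- bias_relu_((U %*% bk$W2) + h, bk$b2)
    if (keep_cache) cache$blocks[[k]] <- list(h_in = h, U = U, h_out = hnew)
    h <- hnew
  }
  y <- drop(h %*% p$Wout + p$bout)
  if (keep_cache) {
    cache$h_last <- h
    list(y = y, cache = cache)
  } else y
}

mlp_backward <- function(p, cache, dy) {
  n <- length(dy)
  g <- list(W0 = NULL, b0 = NULL, blocks = vector("list", length(p$blocks)),
            Wout = NULL, bout = NULL)
  h <- cache$h_last
  g$Wout <- crossprod(h, dy)
  g$bout <- sum(dy)
  dh <- outer(dy, drop(p$Wout))  # n x hidden
  for (k in rev(seq_along(p$blocks))) {
    bk <- p$blocks[[k]]
    ck <- cache$blocks[[k]]
    mul_relumask_cpp(dh, ck$h_out)
    dZres <- dh
    g$blocks[[k]] <- list(
      W2 = crossprod(ck$U, dZres), b2 = colSums(dZres),
      W1 = NULL, b1 = NULL)
    dU <- tcrossprod(dZres, bk$W2)
    mul_relumask_cpp(dU, ck$U)
    g$blocks[[k]]$W1 <- crossprod(ck$h_in, dU)
    g$blocks[[k]]$b1 <- colSums(dU)
    dh <- dh + tcrossprod(dU, bk$W1)
  }
  mul_relumask_cpp(dh, cache$A0)
  g$W0 <- crossprod(cache$X, dh)
  g$b0 <- colSums(dh)
  # reorder block fields to match parameter layout
  for (k in seq_along(g$blocks)) {
    g$blocks[[k]] <- g$blocks[[k]][c("W1", "b1", "W2", "b2")]
  }
  g[c("W0", "b0", "blocks", "Wout", "bout")]
}

# ---- 1D CNN over tokenized SMILES ----------------------------------------

conv_im2col <- function(X, n, L, kernel) im2col_cpp(X, n, L, kernel)

conv_col2im <- function(dXcol, n, L, kernel, C_in) {
  col2im_cpp(dXcol, n, L, kernel, C_in)
}

cnn_forward <- function(p, idx, SP, keep_cache = FALSE) {
  n <- nrow(idx); L <- ncol(idx)
  kernel <- nrow(p$Wc1) / ncol(p$E)
  flat <- as.integer(idx)           # position-major blocks of n
  mask <- as.numeric(flat > 0)
  V <- embed_gather_cpp(p$E, flat)                   # (n*L) x embed
  X1col <- conv_im2col(V, n, L, kernel)
  A1 <- bias_relu_(X1col %*% p$Wc1, p$bc1)           # (n*L) x C1
  mul_rowmask_cpp(A1, mask)
  # max-pool stride 2 over positions (L even)
  L2 <- L %/% 2
  mp <- maxpool2_cpp(A1, n, L2)
  A1p <- mp$out                                      # (n*L2) x C1
  mask2 <- {
    m2 <- matrix(mask, n, L)
    as.numeric(pmax(m2[, seq(1, L, 2), drop = FALSE],
                    m2[, seq(2, L, 2), drop = FALSE]))
  }
  X2col <- conv_im2col(A1p, n, L2, kernel)
  A2 <- bias_relu_(X2col %*% p$Wc2, p$bc2)           # (n*L2) x C2
  mul_rowmask_cpp(A2, mask2)
  # global max + mean pooling over positions
  gp <- global_pool_cpp(A2, mask2, n, L2)
  H <- cbind(gp$M, gp$S, SP)
  Ad <- bias_relu_(H %*% p$Wd, p$bd)
  y <- drop(Ad %*% p$Wout + p$bout)
  if (!keep_cache) return(y)
  list(y = y, cache = list(flat = flat, mask = mask, V = V,
                           X1col = X1col, A1 = A1, sel = mp$sel,
                           A1p = A1p, mask2 = mask2, X2col = X2col,
                           A2 = A2, amax = gp$amax, len = gp$len,
                           H = H, Ad = Ad,
                           n = n, L = L, L2 = L2, kernel = kernel))
}

cnn_backward <- function(p, cache, dy) {
  n <- cache$n; L <- cache$L; L2 <- cache$L2; kernel <- cache$kernel
  C2 <- ncol(cache$A2); C1 <- ncol(cache$A1)
  g <- list(E = NULL, Wc1 = NULL, bc1 = NULL, Wc2 = NULL, bc2 = NULL,
            Wd = NULL, bd = NULL, Wout = NULL, bout = NULL)
  g$Wout <- crossprod(cache$Ad, dy)
  g$bout <- sum(dy)
  dAd <- outer(dy, drop(p$Wout))
  mul_relumask_cpp(dAd, cache$Ad)
  g$Wd <- crossprod(cache$H, dAd)
  g$bd <- colSums(dAd)
  dH <- tcrossprod(dAd, p$Wd)
  dM <- dH[, 1:C2, drop = FALSE]
  dSmean <- dH[, (C2 + 1):(2 * C2), drop = FALSE]
  dA2 <- global_pool_bwd_cpp(dM, dSmean, cache$amax, cache$len, n, L2)
  # valid positions and relu gating (masked positions have A2 == 0)
  mul_relumask_cpp(dA2, cache$A2)
  g$Wc2 <- crossprod(cache$X2col, dA2)
  g$bc2 <- colSums(dA2)
  dX2col <- tcrossprod(dA2, p$Wc2)
  dA1p <- conv_col2im(dX2col, n, L2, kernel, C1)
  dA1 <- maxpool2_bwd_cpp(dA1p, cache$sel, n, L2)
  mul_relumask_cpp(dA1, cache$A1)
  g$Wc1 <- crossprod(cache$X1col, dA1)
  g$bc1 <- colSums(dA1)
  dX1col <- tcrossprod(dA1, p$Wc1)
  dV <- conv_col2im(dX1col, n, L, kernel, ncol(p$E))
  g$E <- embed_scatter_cpp(dV, cache$flat, nrow(p$E))
  g
}

# ---- shared training loop -------------------------------------------------

# forward/backward dispatch on a prepared data list
net_forward <- function(kind, params, data, rows, keep_cache = FALSE) {
  if (kind == "mlp") {
    mlp_forward(params, data$X[rows, , drop = FALSE], keep_cache)
  } else {
    cnn_forward(params, data$idx[rows, , drop = FALSE],
                data$SP[rows, , drop = FALSE], keep_cache)
  }
}

net_backward <- function(kind, params, cache, dy) {
  if (kind == "mlp") mlp_backward(params, cache, dy) else
    cnn_backward(params, cache, dy)
}

# Predict in batches to bound memory
net_predict_scaled <- function(kind, params, data, rows = NULL, batch = 4096) {
  n <- if (kind == "mlp") nrow(data$X) else nrow(data$idx)
  rows <- rows %||% seq_len(n)
  out <- numeric(length(rows))
  for (s in split(seq_along(rows), ceiling(seq_along(rows) / batch))) {
    out[s] <- net_forward(kind, params, data, rows[s], keep_cache = FALSE)
  }
  out
}

# Adam/MAE mini-batch training with periodic validation checkpoints.
# Returns final params, best-validation params and the checkpoint history.
train_loop <- function(kind, params, data, y, train_rows, val_rows,
                       iterations, batch_size, checkpoint_every, lr, seed) {
  state <- adam_new(params)
  history <- list()
  best <- list(params = params, score = Inf, iteration = 0L)
  validate <- function(it, p) {
    if (length(val_rows) == 0) return(invisible(NULL))
    pv <- net_predict_scaled(kind, p, data, val_rows)
    score <- mean(abs(pv - y[val_rows]))
    history[[length(history) + 1]] <<- tibble(iteration = it, val_mae = score)
    if (score < best$score) {
      best <<- list(params = param_copy(p), score = score, iteration = it)
    }
    invisible(NULL)
  }
  batch_size <- min(batch_size, length(train_rows))
  params <- param_copy(params)  # private copy: updates run in place
  with_seed_(derive_seed(seed, paste0("train-", kind)), {
    order_pool <- sample(train_rows)
    cursor <- 1
    if (iterations > 0) validate(0L, params)
    for (it in seq_len(iterations)) {
      if (cursor + batch_size - 1 > length(order_pool)) {
        order_pool <- sample(train_rows)
        cursor <- 1
      }
      rows <- order_pool[cursor:(cursor + batch_size - 1)]
      cursor <- cursor + batch_size
      fb <- net_forward(kind, params, data, rows, keep_cache = TRUE)
      resid <- fb$y - y[rows]
      dy <- sign(resid) / length(rows)
      grads <- net_backward(kind, params, fb$cache, dy)
      state$t <- state$t + 1
      adam_update_nested(params, grads, state$m, state$v, state$t, lr)
      if (it %% checkpoint_every == 0 ||
          (it == iterations && iterations %% checkpoint_every != 0)) {
        validate(it, params)
      }
    }
  })
  if (iterations == 0) best <- list(params = params, score = NA_real_, iteration = 0L)
  list(final_params = param_copy(params), best_params = best$params,
       best_iteration = best$iteration,
       history = if (length(history)) dplyr::bind_rows(history) else
         tibble(iteration = integer(), val_mae = numeric()))
}
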