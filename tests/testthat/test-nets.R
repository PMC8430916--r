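numeric_grad <- function(loss, p, path_get, path_set, eps = 1e-6) {
  (loss(path_set(p, path_get(p) + eps)) - loss(path_set(p, path_get(p) - eps))) /
    (2 * eps)
}

test_that("MLP backpropagation matches numerical gradients", {
  set.seed(42)
  p <- ristack:::init_mlp_params(7, 11, 2, seed = 3)
  X <- matrix(rnorm(5 * 7), 5); y <- rnorm(5)
  loss <- function(q) mean(abs(ristack:::mlp_forward(q, X) - y))
  fb <- ristack:::mlp_forward(p, X, keep_cache = TRUE)
  g <- ristack:::mlp_backward(p, fb$cache, sign(fb$y - y) / 5)
  cases <- list(
    list(function(q) q$W0[2, 3], function(q, v) { q$W0[2, 3] <- v; q },
         g$W0[2, 3]),
    list(function(q) q$blocks[[1]]$b1[4],
         function(q, v) { q$blocks[[1]]$b1[4] <- v; q }, g$blocks[[1]]$b1[4]),
    list(function(q) q$blocks[[2]]$W2[1, 2],
         function(q, v) { q$blocks[[2]]$W2[1, 2] <- v; q },
         g$blocks[[2]]$W2[1, 2]),
    list(function(q) q$Wout[5, 1], function(q, v) { q$Wout[5, 1] <- v; q },
         g$Wout[5, 1]),
    list(function(q) q$bout, function(q, v) { q$bout <- v; q }, g$bout))
  for (cs in cases) {
    expect_equal(numeric_grad(loss, p, cs[[1]], cs[[2]]), cs[[3]],
                 tolerance = 1e-5)
  }
})

test_that("CNN backpropagation matches numerical gradients", {
  set.seed(7)
  A <- 12
  p <- ristack:::init_cnn_params(A, 4, c(3, 5), 5, 6, 4, seed = 9)
  idx <- matrix(sample(0:A, 6 * 10, replace = TRUE), 6, 10)
  idx[, 1:3] <- matrix(sample(1:A, 18, replace = TRUE), 6)
  SP <- matrix(rnorm(24), 6); y <- rnorm(6)
  loss <- function(q) mean(abs(ristack:::cnn_forward(q, idx, SP) - y))
  fb <- ristack:::cnn_forward(p, idx, SP, keep_cache = TRUE)
  g <- ristack:::cnn_backward(p, fb$cache, sign(fb$y - y) / 6)
  cases <- list(
    list(function(q) q$E[3, 2], function(q, v) { q$E[3, 2] <- v; q }, g$E[3, 2]),
    list(function(q) q$Wc1[7, 2], function(q, v) { q$Wc1[7, 2] <- v; q },
         g$Wc1[7, 2]),
    list(function(q) q$bc1[1], function(q, v) { q$bc1[1] <- v; q }, g$bc1[1]),
    list(function(q) q$Wc2[4, 3], function(q, v) { q$Wc2[4, 3] <- v; q },
         g$Wc2[4, 3]),
    list(function(q) q$Wd[2, 2], function(q, v) { q$Wd[2, 2] <- v; q },
         g$Wd[2, 2]),
    list(function(q) q$Wout[3, 1], function(q, v) { q$Wout[3, 1] <- v; q },
         g$Wout[3, 1]))
  for (cs in cases) {
    expect_equal(numeric_grad(loss, p, cs[[1]], cs[[2]]), cs[[3]],
                 tolerance = 1e-5)
  }
})

test_that("training on a constant target converges to that constant", {
  rec <- dplyr::filter(tiny_records(), family == "non-polar")
  rec$ri <- 1000
  net <- train_base(rec, net_spec("mlp", hidden = 24, blocks = 1),
                    train_protocol(iterations = 1200, checkpoint_every = 300,
                                   seed = 5, stage = "base"))
  pred <- predict_ri(net, rec$smiles[1:10], rec$phase[1:10])
  expect_true(all(abs(pred$ri_pred / 1000 - 1) < 0.05))
})

test_that("training is deterministic under a fixed seed", {
  rec <- dplyr::filter(tiny_records(), family == "non-polar")
  proto <- train_protocol(iterations = 150, checkpoint_every = 50, seed = 77,
                          stage = "base")
  n1 <- train_base(rec, net_spec("mlp", hidden = 24, blocks = 1), proto)
  n2 <- train_base(rec, net_spec("mlp", hidden = 24, blocks = 1), proto)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$best_params, n2$best_params)
})

test_that("validation loss improves over training and best checkpoint is the minimum", {
  net <- tiny_mlp()
  h <- net$history
  expect_gt(nrow(h), 2)
  expect_lt(dplyr::last(h$val_mae), h$val_mae[1])
  expect_equal(min(h$val_mae),
               h$val_mae[h$iteration == net$best_iteration])
})

test_that("transfer learning conserves shapes; zero-iteration transfer is the identity", {
  base <- tiny_mlp()
  po <- dplyr::filter(tiny_records(), family == "polar")
  frozen <- transfer_train(base, po, train_protocol(iterations = 0, seed = 1,
                                                    stage = "transfer"))
  expect_identical(frozen$best_params, base$final_params)
  expect_equal(frozen$family, "polar")
  moved <- transfer_train(base, po,
                          train_protocol(iterations = 60, seed = 2,
                                         checkpoint_every = 30,
                                         stage = "transfer"))
  expect_equal(ristack:::param_count(moved$best_params),
               ristack:::param_count(base$best_params))
  wrong <- ristack:::init_mlp_params(10, 4, 1, seed = 1)
  expect_error(
    train_base(po, net_spec("mlp", hidden = 24, blocks = 1),
               train_protocol(iterations = 10, seed = 1), family = "polar",
               init = wrong),
    "shape-compatible")
})

test_that("predictions are invariant to the SMILES rendering", {
  net <- tiny_mlp()
  p <- predict_ri(net, c("CCC(C)O", "CC(O)CC"), "DB-5")
  expect_equal(p$ri_pred[1], p$ri_pred[2])
})

test_that("ensemble averaging is the arithmetic mean", {
  expect_equal(ensemble_average(c(1000, 1100)), 1050)
  expect_equal(ensemble_average(c(1000, 1100), c(1100, 1300)), c(1050, 1200))
  expect_equal(ensemble_average(5), 5)
  expect_error(ensemble_average(), "at least one")
})

test_that("the predicted-RI feature block is 114 wide, scaled and stable", {
  nets <- list(cnn = constant_net("cnn", 1.0),
               mlp = constant_net("mlp", 1.0),
               cnn_polar = constant_net("cnn", 1.0, family = "polar"),
               mlp_polar = constant_net("mlp", 1.0, family = "polar"))
  blk <- ri_feature_block(nets, c("CCO", "CCCC(=O)OC"))
  expect_equal(dim(blk), c(2, 114))
  expect_equal(unname(blk[1, ]), rep(1, 114))  # constant nets: 1000/1000
  blk2 <- ri_feature_block(nets, c("CCO", "CCCC(=O)OC"))
  expect_identical(colnames(blk), colnames(blk2))
  expect_identical(blk, blk2)
  expect_error(ri_feature_block(nets[1:3], "CCO"), "incomplete ensemble")
  # constant net also round-trips through predict_ri with the x1000 scale
  expect_equal(predict_ri(nets$mlp, "CCO", "DB-5")$ri_pred, 1000)
})
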