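test_that("hyperparameter defaults are the published working point", {
  hp <- svr_hyperparams()
  expect_equal(hp$sigma, 31.0)
  expect_equal(hp$epsilon, 0.82)
  expect_equal(hp$C, 31000)
  expect_equal(hp$tolerance, 2.7)
  expect_error(svr_hyperparams(sigma = -1))
})

test_that("the exponential kernel is symmetric with unit diagonal", {
  k <- ristack:::kernlab_kernel(svr_hyperparams())
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(drop(k(x, x)), 1)
  expect_equal(drop(k(x, y)), drop(k(y, x)))
  expect_equal(drop(k(x, y)), exp(-sqrt(sum((x - y)^2)) / 31))
  expect_gt(drop(k(x, y)), 0)
})

test_that("feature assembly yields the 441-feature contract", {
  blk <- matrix(rnorm(3 * 114), 3, dimnames = list(NULL, paste0("b", 1:114)))
  dsc <- matrix(rnorm(3 * 327), 3, dimnames = list(NULL, paste0("d", 1:327)))
  f <- assemble_features(blk, dsc)
  expect_equal(ncol(f), 441)
  expect_equal(unname(f[, 1:114]), unname(blk))
  z <- assemble_features(matrix(0, 1, 114), matrix(0, 1, 327))
  expect_equal(unname(z), matrix(0, 1, 441))
  expect_error(assemble_features(blk[, 1:100], dsc), "114")
  expect_error(assemble_features(blk, dsc[, 1:300]), "327")
})

test_that("targets inside one tube give a flat (bias-only) model", {
  X <- matrix(rnorm(10), 2, 5)
  m <- train_stack(X, c(1000, 1000.5))
  expect_equal(m$kind, "bias")
  pred <- predict_stack(m, X)
  expect_true(all(abs(pred - c(1000, 1000.5)) <= 0.82))
  expect_equal(as.vector(pred), rep(1000.25, 2))
  expect_true(kkt_check(m, X, c(1000, 1000.5))$ok)
  # one-point training set with epsilon = 0 reproduces its target
  m1 <- train_stack(X[1, , drop = FALSE], 1234,
                    svr_hyperparams(epsilon = 0))
  expect_equal(as.vector(predict_stack(m1, X[1, , drop = FALSE])), 1234)
})

test_that("a bias-only model predicts 1000 * b everywhere", {
  X <- matrix(rnorm(20), 4, 5)
  m <- train_stack(X, rep(900, 4))
  expect_equal(m$kind, "bias")
  expect_equal(as.vector(predict_stack(m, matrix(rnorm(10), 2, 5))),
               rep(m$b * 1000, 2))
})

test_that("KKT and tube invariants hold on real fits", {
  set.seed(20)
  for (s in 1:3) {
    X <- matrix(rnorm(80 * 6), 80)
    y <- 1000 * (1 + 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(80, sd = 0.02))
    m <- train_stack(X, y)
    expect_equal(m$kind, "svr")
    expect_true(all(abs(m$coef) <= m$hp$C * (1 + 1e-6)))
    k <- kkt_check(m, X, y)
    expect_true(k$ok)
  }
})

test_that("duplicated training data leaves the fitted function unchanged", {
  set.seed(4)
  X <- matrix(rnorm(40 * 5), 40)
  y <- 1000 * (2 + X[, 1] + rnorm(40, sd = 0.05))
  m1 <- train_stack(X, y)
  m2 <- train_stack(rbind(X, X), c(y, y))
  Xnew <- matrix(rnorm(10 * 5), 10)
  expect_equal(predict_stack(m1, Xnew), predict_stack(m2, Xnew),
               tolerance = 0.02)
})

test_that("predictions are deterministic and unit metadata flows through", {
  set.seed(6)
  X <- matrix(rnorm(30 * 4), 30)
  y <- 1000 + 200 * X[, 1] + rnorm(30, 5)
  m <- train_stack(X, y, unit = "ms")
  p1 <- predict_stack(m, X)
  p2 <- predict_stack(m, X)
  expect_identical(p1, p2)
  expect_equal(attr(p1, "unit"), "ms")
  expect_error(predict_stack(m, X[, 1:3]), "layout")
})

test_that("conflicting duplicate features warn but fit proceeds", {
  X <- matrix(1, 4, 3)
  X[3:4, ] <- 2
  expect_warning(m <- train_stack(X, c(1000, 1400, 800, 1200)), "conflicting")
  expect_s3_class(m, "ri_stack")
})

test_that("the literal printed protocol (scaled units) degenerates to a near-flat fit", {
  set.seed(9)
  X <- matrix(rnorm(60 * 5), 60)
  y <- 1000 * (1 + 0.8 * X[, 1])  # scaled spread ~ +-2.4, tube 0.82
  m_scaled <- train_stack(X, y, svr_hyperparams(epsilon_units = "scaled"))
  m_index <- train_stack(X, y, svr_hyperparams(epsilon_units = "index"))
  mae_scaled <- mean(abs(predict_stack(m_scaled, X) - y))
  mae_index <- mean(abs(predict_stack(m_index, X) - y))
  expect_lt(mae_index, mae_scaled)
})
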