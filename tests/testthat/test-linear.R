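test_that("group-contribution fit recovers an exact additive model", {
  set.seed(5)
  counts <- cbind(g1 = rpois(40, 2), g2 = rpois(40, 1), g3 = rpois(40, 3))
  y <- 400 + 100 * counts[, "g1"]
  fit <- fit_group_contributions(tibble::tibble(smiles = NA, ri = y), counts)
  expect_equal(fit$intercept, 400, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["g1"]), 100, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["g2"]), 0, tolerance = 1e-6)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-6)
})

test_that("rank-deficient designs fall back to the pseudoinverse solution", {
  smiles <- c("CCO", "CCCO", "CCCCO", "CC(C)O", "CCC(C)O", "CCOC", "CCCOC",
              "CC(=O)OC", "CC(=O)OCC", "CCCC(=O)OC")
  counts <- functional_group_counts(smiles)
  y <- 380 + 90 * counts[, "fg_hydroxyl"] + 5 * counts[, "fg_methyl"]
  w <- capture_warnings(
    fit <- fit_group_contributions(tibble::tibble(smiles = smiles, ri = y),
                                   counts))
  expect_true(any(grepl("minimum-norm", w)))
  # oracle: explicit SVD pseudoinverse of the same design
  X <- cbind(1, counts)
  beta_oracle <- drop(MASS::ginv(X) %*% y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), beta_oracle,
               tolerance = 1e-6)
  expect_equal(unname(predict(fit, counts = counts)), unname(y),
               tolerance = 1e-6)
})

test_that("group-contribution fit ignores record order; constant targets give flat model", {
  set.seed(8)
  counts <- cbind(a = rpois(30, 2), b = rpois(30, 1))
  y <- 500 + 20 * counts[, "a"] + rnorm(30, sd = 5)
  f1 <- fit_group_contributions(tibble::tibble(smiles = NA, ri = y), counts)
  ord <- sample(30)
  f2 <- fit_group_contributions(tibble::tibble(smiles = NA, ri = y[ord]),
                                counts[ord, ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  flat <- fit_group_contributions(tibble::tibble(smiles = NA, ri = rep(800, 30)),
                                  counts)
  expect_equal(flat$intercept, 800, tolerance = 1e-9)
  expect_equal(max(abs(flat$coefficients)), 0, tolerance = 1e-9)
})

test_that("greedy combination recovers an exact two-phase mixture", {
  set.seed(12)
  X <- matrix(runif(200 * 4, 400, 3000), 200,
              dimnames = list(NULL, c("P1", "P2", "P3", "P4")))
  y <- 0.3 * X[, "P1"] + 0.7 * X[, "P2"]
  m <- greedy_sp_combination(X, y, gain_threshold = 5)
  expect_setequal(m$terms$phase, c("P1", "P2"))
  expect_equal(sort(m$terms$coefficient), c(0.3, 0.7), tolerance = 1e-6)
  resid_mae <- mean(abs(y - apply_combo(m, as.data.frame(X))))
  expect_lt(resid_mae, 1e-6)
  oracle <- brute_force_combo(X, y)
  expect_setequal(m$terms$phase, oracle$cols)
  expect_equal(resid_mae, oracle$mae, tolerance = 1e-9)
})

test_that("greedy combination base cases and the five-term cap", {
  set.seed(13)
  X <- matrix(runif(100 * 7, 500, 2500), 100,
              dimnames = list(NULL, paste0("P", 1:7)))
  one <- greedy_sp_combination(X, X[, "P3"], gain_threshold = 5)
  expect_equal(one$terms$phase, "P3")
  expect_equal(one$terms$coefficient, 1, tolerance = 1e-9)
  # six informative candidates, zero threshold: still at most five terms
  y <- X[, 1:6] %*% c(0.1, 0.2, 0.15, 0.25, 0.2, 0.1)
  capped <- greedy_sp_combination(X, drop(y), gain_threshold = 0)
  expect_lte(nrow(capped$terms), 5)
  expect_error(greedy_sp_combination(X[, 0], drop(y)), "non-empty")
})

test_that("exclusion pairs keep near-identical phases apart", {
  set.seed(14)
  X <- matrix(runif(150 * 3, 400, 3000), 150,
              dimnames = list(NULL, c("A", "B", "C")))
  X[, "B"] <- X[, "A"] + rnorm(150, sd = 1)
  y <- 0.5 * X[, "A"] + 0.5 * X[, "C"] + rnorm(150, sd = 2)
  m <- greedy_sp_combination(X, y, gain_threshold = 0,
                             exclude = rbind(c("A", "B")))
  expect_false(all(c("A", "B") %in% m$terms$phase))
})

test_that("apply_combo evaluates the printed equations and guards inputs", {
  eqs <- builtin_combo_equations()
  expect_equal(apply_combo(eqs[["DB-1701"]],
                           c("DB-624" = 1000, "DB-WAX" = 1000)), 1025.9)
  inputs5 <- c(Squalane = 1000, "DB-1" = 1000, "DB-5" = 1000,
               "DB-624" = 1000, "DB-WAX" = 1000)
  expect_equal(apply_combo(eqs[["DB-210"]], inputs5), 1059.2)
  expect_equal(apply_combo(eqs[["DB-210"]], inputs5 * 0), 0)
  expect_error(apply_combo(eqs[["DB-1701"]], c("DB-624" = 1000)), "missing")
  expect_equal(nrow(eqs[["DB-1701"]]$terms), 2)
  expect_equal(nrow(eqs[["DB-210"]]$terms), 5)
  expect_identical(eqs[["DB-1701"]]$terms$coefficient, c(0.949, 0.0769))
  expect_identical(eqs[["DB-210"]]$terms$coefficient,
                   c(-3.3267, -0.3007, 3.0737, 1.72, -0.1071))
})
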