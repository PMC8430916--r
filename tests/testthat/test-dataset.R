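test_that("admission rejects whitelist violations, oversize molecules and n-alkanes", {
  rec <- tibble::tibble(
    smiles = c("Cc1ccccc1", "CCCCCCCCCC", "C[Se]CCC(N)C(=O)O", "CCO",
               "bad(((smiles"),
    ri = c(760, 1000, 1500, 430, 100))
  adm <- admit_records(rec)
  expect_equal(adm$smiles, c("Cc1ccccc1", "CCO"))
  rej <- rejections(adm)
  expect_setequal(rej$reason,
                  c("n-alkane", "element outside whitelist", "parse failure"))
  big <- admit_records(tibble::tibble(smiles = paste0(strrep("C", 120), "O")))
  expect_equal(rejections(big)$reason, "heavy-atom cap exceeded")
})

test_that("exclusion is compound-complete and stereo-collapsed", {
  train <- tibble::tibble(
    smiles = c("CC(=C)[C@@H]1CC=C(C)CC1", "CCO", "CCCO"),
    ri = c(1030, 430, 550))
  test <- tibble::tibble(smiles = "CC(=C)[C@H]1CC=C(C)CC1", ri = 1030)
  out <- exclude_compounds(train, test)
  expect_equal(out$smiles, c("CCO", "CCCO"))
  expect_length(intersect(out$compound_key, compound_key(test$smiles)), 0)
  # disjoint sets: unchanged
  out2 <- exclude_compounds(train, tibble::tibble(smiles = "CCCCCC(=O)C"))
  expect_equal(nrow(out2), 3)
})

test_that("k-fold assignment partitions compounds, not records", {
  rec <- tiny_records()
  f <- kfold_compounds(rec, k = 5, seed = 9)
  expect_true(all(f$fold %in% 1:5))
  per_key <- tapply(f$fold, f$compound_key, function(x) length(unique(x)))
  expect_true(all(per_key == 1))
  sizes <- table(tapply(f$fold, f$compound_key, unique))
  expect_true(max(sizes) - min(sizes) <= 1)
  f2 <- kfold_compounds(rec, k = 5, seed = 9)
  expect_identical(f$fold, f2$fold)
  expect_error(kfold_compounds(rec[1:3, ], k = 200), "fewer compounds")
})

test_that("metric suite matches hand arithmetic", {
  m <- suppressWarnings(ri_metrics(c(1010, 990, 1030), c(1000, 1000, 1000)))
  expect_equal(m$mae, 50 / 3, tolerance = 1e-12)
  expect_equal(m$mdae, 10)
  expect_equal(m$rmse, sqrt(1100 / 3), tolerance = 1e-12)
  expect_equal(m$mpe, 5 / 3, tolerance = 1e-12)
  expect_equal(m$mdpe, 1)
  expect_true(is.na(m$r2))
  expect_warning(ri_metrics(c(1, 2), c(5, 5)), "constant")
  perfect <- ri_metrics(c(100, 200, 300), c(100, 200, 300))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
})

test_that("metric inequalities and invariances hold on random data", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    ref <- runif(n, 300, 4000)
    pred <- ref + rnorm(n, sd = runif(1, 1, 100))
    m <- ri_metrics(pred, ref)
    expect_gte(m$rmse, m$mae)
    perm <- sample(n)
    mp <- ri_metrics(pred[perm], ref[perm])
    expect_equal(m, mp)
    # coverage90 never decreases when a larger error is appended
    worse <- ri_metrics(c(pred, ref[1] + 10 * (m$coverage90 + 1)), c(ref, ref[1]))
    expect_gte(worse$coverage90, m$coverage90 - 1e-9)
  }
})
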