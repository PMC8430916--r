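test_that("canonicalization gives one compound key per constitution", {
  p <- parse_molecules(c("CCO", "OCC"))
  expect_true(all(p$valid))
  expect_equal(p$compound_key[1], p$compound_key[2])
  expect_equal(p$canonical_smiles[1], p$canonical_smiles[2])
})

test_that("stereoisomers and isotopomers collapse to the same compound key", {
  cis_trans <- compound_key(c("C/C=C/C", "C/C=C\\C"))
  expect_equal(cis_trans[1], cis_trans[2])
  optical <- compound_key(c("C[C@H](O)CC", "C[C@@H](O)CC", "CC(O)CC"))
  expect_length(unique(optical), 1)
  isotopes <- compound_key(c("[13CH3]CO", "CCO"))
  expect_equal(isotopes[1], isotopes[2])
})

test_that("malformed SMILES are rejected, not fatal", {
  p <- parse_molecules(c("CCO", "not_a_smiles", "CCC"))
  expect_equal(p$valid, c(TRUE, FALSE, TRUE))
  expect_match(p$error[2], "parse failure")
  expect_equal(p$compound_key[1], "CCO")
})

test_that("n-alkane detection is definitional", {
  expect_equal(is_n_alkane(c("CCCCCC", "CC(C)CCC", "C1CCCCC1", "CCO", "C=CCC")),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("CNN one-hot grid pads with zeros and round-trips", {
  g <- cnn_encode("CCO", L_max = 10)
  expect_equal(dim(g), c(length(smiles_alphabet()), 10))
  expect_equal(colSums(g), c(1, 1, 1, rep(0, 7)))
  expect_true(all(colSums(g)[colSums(g) > 0] == 1))
  expect_error(cnn_encode(strrep("C", 30), L_max = 10), "exceeding")
})

test_that("decoding occupied columns reproduces canonical SMILES (100 molecules)", {
  lib <- generate_library(100, seed = 77)
  can <- parse_molecules(lib$smiles)$canonical_smiles
  for (s in can) {
    g <- cnn_encode(s, L_max = 64)
    expect_equal(ristack:::cnn_decode(g), s)
  }
})

test_that("tokens outside the alphabet are an error", {
  expect_error(ristack:::tokenize_smiles("C?O"), "alphabet")
})

test_that("descriptors are invariant to the SMILES rendering of a molecule", {
  renderings <- list(
    c("CCC(C)O", "CC(O)CC", "OC(C)CC", "C(C)(O)CC"),
    c("c1ccccc1CC", "CCc1ccccc1", "C(c1ccccc1)C"),
    c("CC(=O)OCC", "CCOC(C)=O", "O=C(C)OCC")
  )
  for (forms in renderings) {
    D <- descriptor_matrix(forms)
    for (i in 2:nrow(D)) expect_equal(D[i, ], D[1, ])
  }
})
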