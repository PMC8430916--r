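test_that("the descriptor manifest pins 243 general + 84 group counters", {
  man <- default_descriptor_manifest()
  expect_equal(nrow(man), 327)
  expect_equal(sum(man$class != "fg_smarts"), 243)
  expect_equal(sum(man$class == "fg_smarts"), 84)
  expect_equal(man$name, ristack:::descriptor_definitions()$name)
  expect_true(all(is.finite(man$scale)) && all(man$scale != 0))
})

test_that("descriptor vectors have length 327 and are deterministic", {
  v1 <- descriptor_vector("CCCC(=O)OCC")
  v2 <- descriptor_vector("CCCC(=O)OCC")
  expect_length(v1, 327)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
})

test_that("functional-group counters count what they claim", {
  fg <- functional_group_counts(c("c1ccccc1", "CCO", "OCC(O)CO",
                                  "CC(=O)OCC", "CC"))
  expect_equal(unname(fg[, "fg_hydroxyl"]), c(0L, 1L, 3L, 0L, 0L))
  expect_equal(unname(fg[, "fg_ester"]), c(0L, 0L, 0L, 1L, 0L))
  expect_true(all(fg >= 0))
  expect_true(is.integer(fg))
  # ethane: only alkyl/chain counters may fire
  eth <- fg[5, fg[5, ] > 0]
  expect_true(all(names(eth) %in% c("fg_methyl")))
})

test_that("raw counter block sits unscaled inside the full vector pipeline", {
  man <- default_descriptor_manifest()
  raw <- descriptor_matrix("OCC(O)CO", man, scaled = FALSE)
  scl <- descriptor_matrix("OCC(O)CO", man, scaled = TRUE)
  j <- which(man$name == "fg_hydroxyl")
  expect_equal(unname(raw[1, j]), 3)
  expect_equal(unname(scl[1, j]), (3 - man$center[j]) / man$scale[j])
})
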