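test_that("default registry geometry: 36 non-polar, 21 polar, length 38", {
  reg <- default_phase_registry()
  expect_length(reg$nonpolar_types, 36)
  expect_length(reg$polar_types, 21)
  expect_equal(reg$encoding_length, 38L)
  expect_equal(reg$polar_types[21], "Other polar")
  expect_false(anyDuplicated(reg$nonpolar_types) > 0)
})

test_that("polar encoding is strictly one-hot with an Other-polar fallback", {
  e <- sp_encode(c("DB-WAX", "some obscure PEG variant"), "polar")
  expect_equal(dim(e), c(2, 38))
  expect_equal(rowSums(e), c(1, 1))
  expect_equal(attr(e, "active_index")[2], 21)
  expect_true(all(e %in% c(0, 1)))
})

test_that("the non-polar catalog is closed and injective", {
  reg <- default_phase_registry()
  expect_error(sp_encode("mystery phase", "non-polar"), "closed")
  e <- sp_encode(reg$nonpolar_types, "non-polar")
  expect_equal(attr(e, "active_index"), seq_len(36))
  ep <- sp_encode(reg$polar_types, "polar")
  expect_equal(attr(ep, "active_index"), seq_len(21))
})
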