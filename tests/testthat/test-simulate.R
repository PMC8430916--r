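test_that("library generation is reproducible and structure-linked", {
  l1 <- generate_library(80, seed = 3)
  l2 <- generate_library(80, seed = 3)
  expect_identical(l1, l2)
  expect_false(any(duplicated(l1$smiles)))
  expect_true(all(l1$L > 0))
  # no n-alkanes in the analyte list (they form the reference ladder)
  expect_false(any(grepl("^C+$", l1$smiles)))
  # donor-free classes carry exactly zero hydrogen-bond acidity
  no_donor <- l1$chem_class %in% c("ester", "ketone", "aldehyde", "ether",
                                   "alkene", "branched_alkane", "nitrile",
                                   "cycloalkane", "alkylbenzene")
  expect_true(all(l1$A[no_donor] == 0))
})

test_that("homologs gain size parameter L with chain length", {
  z2 <- ristack:::sim_build_analyte("alcohol", 2, 1)
  z3 <- ristack:::sim_build_analyte("alcohol", 3, 1)
  p2 <- ristack:::sim_abraham_params(z2, rep(0, 5))
  p3 <- ristack:::sim_abraham_params(z3, rep(0, 5))
  expect_equal(z2$smiles, "CCO")
  expect_equal(z3$smiles, "CCCO")
  expect_gt(p3[["L"]], p2[["L"]])
})

test_that("the solvation equation is evaluated exactly and linearly", {
  ph <- tibble::tibble(phase = "P", c = -1, e = 0.2, s = 0.5, a = 1, b = 0.3,
                       l = 0.5)
  an0 <- tibble::tibble(analyte_id = "x", E = 0, S = 0, A = 0, B = 0, L = 0)
  expect_equal(abraham_log_k(an0, ph)$log_k, -1)
  anE <- dplyr::mutate(an0, E = 1)
  expect_equal(abraham_log_k(anE, ph)$log_k, -0.8)
  an2E <- dplyr::mutate(an0, E = 2)
  expect_equal(abraham_log_k(an2E, ph)$log_k - abraham_log_k(anE, ph)$log_k,
               0.2)
})

test_that("Kovats bracketing anchors the ladder and interpolates midpoints", {
  ph <- sim_default_phases()[1, ]
  lad <- dplyr::filter(alkane_ladder(ph), phase == ph$phase)
  i8 <- which(lad$n_carbon == 8)
  expect_equal(kovats_ri(lad$log_k[i8], lad)$ri, 800)
  expect_equal(kovats_ri(lad$log_k[lad$n_carbon == 10], lad)$ri, 1000)
  mid <- (lad$log_k[i8] + lad$log_k[i8 + 1]) / 2
  expect_equal(kovats_ri(mid, lad)$ri, 850)
  expect_false(kovats_ri(mid, lad)$extrapolated)
  below <- kovats_ri(lad$log_k[1] - 1, lad)
  expect_true(below$extrapolated)
  bad <- dplyr::mutate(lad, log_k = rev(log_k))
  expect_error(kovats_ri(mid, bad), "strictly increasing")
})

test_that("corpus noise has the right scale and regenerates bit-identically", {
  lib <- generate_library(50, seed = 21)
  ph <- dplyr::mutate(sim_default_phases(), ri_noise_sd = 0)
  c0 <- build_corpus(lib, ph, seed = 22)
  expect_equal(c0$records$ri,
               c0$truth$ri_true[match(paste(c0$records$analyte_id, c0$records$phase),
                                      paste(c0$truth$analyte_id, c0$truth$phase))])
  c1 <- build_corpus(lib, sim_default_phases(), seed = 23)
  c2 <- build_corpus(lib, sim_default_phases(), seed = 23)
  expect_identical(c1$records, c2$records)
  # half-normal mean of |error|: sd * sqrt(2/pi), checked at 10,000 draws
  ph10 <- dplyr::mutate(sim_default_phases(), ri_noise_sd = 10)
  cbig <- build_corpus(generate_library(1000, seed = 24), ph10,
                       replicates = 1, seed = 25)
  err <- abs(cbig$records$ri -
               cbig$truth$ri_true[match(paste(cbig$records$analyte_id, cbig$records$phase),
                                        paste(cbig$truth$analyte_id, cbig$truth$phase))])
  expect_equal(mean(err), 10 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("polar phases shift polar analytes upward relative to non-polar", {
  lib <- tibble::tibble(
    analyte_id = c("alcohol", "arene"),
    smiles = c("CCCCCO", "CCCc1ccccc1"), chem_class = c("alcohol", "alkylbenzene"),
    n_heavy = c(6, 9), E = c(0.2, 0.6), S = c(0.42, 0.5), A = c(0.37, 0),
    B = c(0.48, 0.14), L = c(3.1, 4.7))
  ph <- dplyr::mutate(sim_default_phases(), ri_noise_sd = 0)
  corp <- build_corpus(lib, ph, seed = 1)
  tr <- corp$truth
  shift <- function(id) {
    tr$ri_true[tr$analyte_id == id & tr$phase == "DB-WAX"] -
      tr$ri_true[tr$analyte_id == id & tr$phase == "Squalane"]
  }
  expect_gt(shift("alcohol"), shift("arene"))
  expect_gt(shift("alcohol"), 0)
})

test_that("a linear-combination phase is the weighted sum in log k", {
  ph <- sim_default_phases()[c(1, 6), ]
  mix <- make_linear_phase(ph, c(0.5, 0.5), "MIX")
  lib <- generate_library(20, seed = 31)
  lk <- abraham_log_k(lib, dplyr::bind_rows(ph, mix))
  wide <- tidyr::pivot_wider(lk, names_from = "phase", values_from = "log_k")
  expect_equal(wide$MIX, 0.5 * wide$Squalane + 0.5 * wide$`DB-WAX`,
               tolerance = 1e-12)
  single <- make_linear_phase(ph[1, ], 1, "COPY")
  expect_equal(unlist(single[, c("c", "e", "s", "a", "b", "l")]),
               unlist(ph[1, c("c", "e", "s", "a", "b", "l")]))
  expect_error(make_linear_phase(ph[0, ], numeric(0), "X"), "at least one")
})
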