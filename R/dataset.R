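#' Admission filtering of retention records
#'
#' Applies the corpus hygiene rules before any training: SMILES must parse;
#' only whitelisted elements are allowed (uncommon elements such as selenium
#' are rejected); molecules above the heavy-atom cap are rejected; and
#' n-alkanes are removed since they define the retention-index scale itself.
#' Rejections are logged, not fatal.
#'
#' @param records Tibble with at least a `smiles` column (typically also
#'   `phase`, `family`, `ri`, `source`).
#' @param whitelist Allowed chemical elements.
#' @param max_heavy Maximum heavy-atom count.
#' @return The admitted records with `canonical_smiles` and `compound_key`
#'   columns added; the rejected rows with a `reason` column are attached as
#'   the `"rejections"` attribute (see [rejections()]).
#' @export
#' @examples
#' r <- admit_records(tibble::tibble(smiles = c("Cc1ccccc1", "CCCCCCCCCC", "C[Se]C")))
#' r$compound_key
#' rejections(r)
admit_records <- function(records,
                          whitelist = c("C", "H", "O", "N", "S", "P", "F",
                                        "Cl", "Br", "I", "Si"),
                          max_heavy = 100) {
  assert_cols(records, "smiles")
  parsed <- parse_molecules(records$smiles)
  reason <- rep(NA_character_, nrow(records))
  reason[!parsed$valid] <- "parse failure"
  ok <- parsed$valid
  if (any(ok)) {
    elems <- smiles_elements(parsed$canonical_smiles[ok])
    bad_elem <- vapply(elems, function(e) any(!e %in% whitelist), logical(1))
    too_big <- vapply(elems, length, integer(1)) > max_heavy
    alkane <- grepl("^C+$", parsed$canonical_smiles[ok])
    r <- rep(NA_character_, sum(ok))
    r[too_big] <- "heavy-atom cap exceeded"
    r[bad_elem] <- "element outside whitelist"
    r[alkane] <- "n-alkane"
    reason[ok] <- r
  }
  out <- records |>
    dplyr::mutate(canonical_smiles = parsed$canonical_smiles,
                  compound_key = parsed$compound_key)
  keep <- is.na(reason)
  rej <- dplyr::mutate(out[!keep, , drop = FALSE], reason = reason[!keep])
  out <- out[keep, , drop = FALSE]
  attr(out, "rejections") <- rej
  out
}

#' @rdname admit_records
#' @param admitted The return value of [admit_records()].
#' @export
rejections <- function(admitted) {
  attr(admitted, "rejections") %||% tibble()
}

# Extract heavy-atom element symbols from canonical SMILES (bracket atoms,
# two-letter organic-subset symbols, then single letters; aromatic lowercase
# maps to its element).
smiles_elements <- function(canonical_smiles) {
  rx <- "\\[[0-9]*([A-Z][a-z]?|[a-z]{1,2})[^]]*\\]|Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s"
  lapply(canonical_smiles, function(s) {
    m <- regmatches(s, gregexpr(rx, s))[[1]]
    vapply(m, function(tok) {
      if (startsWith(tok, "[")) {
        sym <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", tok)
      } else {
        sym <- tok
      }
      first <- substr(sym, 1, 1)
      if (first %in% letters) {
        sym <- paste0(toupper(first), substr(sym, 2, 2))
        sym <- sub("h$", "", sym)  # [nH] etc.
      }
      sym
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Compound-based exclusion of test compounds from a training set
#'
#' Removes from `train` every record whose stereo-collapsed `compound_key`
#' occurs in `test`: exclusion is compound-complete, and because keys
#' collapse stereoisomers and isotopomers, a D-enantiomer in training is
#' removed when the L-enantiomer sits in the test set.
#'
#' @param train,test Record tibbles; a `compound_key` column is computed
#'   from `smiles` when absent.
#' @return `train` without any test compounds.
#' @export
exclude_compounds <- function(train, test) {
  train <- ensure_keys(train)
  test <- ensure_keys(test)
  dplyr::filter(train, !.data$compound_key %in% unique(test$compound_key))
}

ensure_keys <- function(records) {
  if (!"compound_key" %in% names(records)) {
    assert_cols(records, "smiles")
    records$compound_key <- compound_key(records$smiles)
  }
  records
}

#' Compound-based k-fold assignment
#'
#' Partitions compounds (not records) into `k` folds: all records of one
#' compound land in the same fold, so no compound straddles a train/test
#' boundary.
#'
#' @param records Record tibble (keys computed from `smiles` if needed).
#' @param k Number of folds.
#' @param seed Integer seed; the same seed reproduces the same folds.
#' @return `records` with an integer `fold` column in `1:k`.
#' @export
kfold_compounds <- function(records, k = 5, seed = 1) {
  stopifnot(k >= 2)
  records <- ensure_keys(records)
  keys <- unique(records$compound_key)
  if (length(keys) < k) abort("fewer compounds than folds")
  fold_of <- with_seed_(derive_seed(seed, "kfold"), {
    setNames(rep_len(seq_len(k), length(keys))[sample.int(length(keys))], keys)
  })
  dplyr::mutate(records, fold = unname(fold_of[.data$compound_key]))
}

#' Accuracy metric suite for retention predictions
#'
#' Computes the full error panel used to report retention-index accuracy:
#' mean and median absolute error (MAE, MdAE), root-mean-square error
#' (RMSE), mean and median absolute percentage error relative to the
#' reference value (MPE, MdPE, in %), the coefficient of determination
#' `R^2 = 1 - SSres/SStot`, and `coverage90`, the empirical 90th percentile
#' of absolute deviations (90% of records deviate by less than this many
#' index units).
#'
#' @param estimate Numeric vector of predictions.
#' @param truth Numeric vector of reference values (positive for the
#'   percentage metrics).
#' @return A one-row tibble `n, mae, mdae, rmse, mpe, mdpe, r2, coverage90`.
#'   `r2` is `NA` (with a warning) when `truth` is constant.
#' @export
#' @examples
#' ri_metrics(c(1010, 990, 1030), c(1000, 1000, 1000))
ri_metrics <- function(estimate, truth) {
  stopifnot(length(estimate) == length(truth), length(truth) > 0)
  d <- estimate - truth
  ad <- abs(d)
  sstot <- sum((truth - mean(truth))^2)
  r2 <- if (sstot <= 0) {
    warn("reference values are constant: R^2 is undefined")
    NA_real_
  } else 1 - sum(d^2) / sstot
  tibble(n = length(d),
         mae = mean(ad),
         mdae = median(ad),
         rmse = sqrt(mean(d^2)),
         mpe = mean(ad / abs(truth)) * 100,
         mdpe = median(ad / abs(truth)) * 100,
         r2 = r2,
         coverage90 = unname(quantile(ad, 0.9, type = 7)))
}
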