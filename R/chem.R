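#' Parse and canonicalize molecules from SMILES
#'
#' Parses SMILES through OpenBabel (via ChemmineOB), returning the canonical
#' SMILES and a stereo-collapsed `compound_key`. The compound key removes
#' cis/trans and optical stereo descriptors and isotope labels before
#' re-canonicalization, so all stereoisomers (and isotopomers) of one
#' constitution share a single key; compound-based dataset operations
#' (splitting, exclusion, cross-validation) are keyed on it.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with one row per input: `smiles`, `canonical_smiles`,
#'   `compound_key`, `valid` (logical) and `error` (NA or a message).
#'   Invalid SMILES yield `valid = FALSE` rather than an error.
#' @export
#' @examples
#' parse_molecules(c("CCO", "OCC", "C/C=C/C", "C/C=C\\C"))
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles))
  can <- ob_canonical(smiles)
  key <- rep(NA_character_, length(smiles))
  ok <- !is.na(can)
  if (any(ok)) key[ok] <- ob_canonical(strip_stereo(can[ok]))
  tibble(smiles = smiles,
         canonical_smiles = can,
         compound_key = key,
         valid = ok & !is.na(key),
         error = ifelse(ok, NA_character_, "SMILES parse failure"))
}

#' @rdname parse_molecules
#' @export
compound_key <- function(smiles) parse_molecules(smiles)$compound_key

# Remove stereo bond markers, chirality tags and isotope labels from SMILES.
# '@' only occurs as a chirality tag inside brackets, '/' and '\' only as
# cis/trans bond markers, and bracket isotopes are leading digits; bracket
# hydrogen counts are left untouched so valence is preserved.
strip_stereo <- function(smiles) {
  x <- gsub("[/\\\\]", "", smiles)
  x <- gsub("@{1,2}", "", x)
  gsub("\\[[0-9]+", "[", x)
}

# Canonicalize SMILES via OpenBabel. Batch conversion is the fast path; if
# OpenBabel chokes on an invalid entry (it truncates the batch), fall back to
# per-molecule conversion so failures map to NA in place.
ob_canonical <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  one <- function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) "")
    out <- strsplit(out, "\n", fixed = TRUE)[[1]]
    if (length(out) != 1 || !nzchar(out)) return(NA_character_)
    sub("\t.*$", "", out)
  }
  batch <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n"))),
    error = function(e) "")
  lines <- strsplit(batch, "\n", fixed = TRUE)[[1]]
  if (length(lines) == length(smiles)) {
    return(sub("\t.*$", "", lines))
  }
  vapply(smiles, one, character(1), USE.NAMES = FALSE)
}

# Build the SDFset and OBMol references for a vector of (valid, canonical)
# SMILES. Returns list(sdf =, obmols =); order follows the input.
mol_handles <- function(canonical_smiles) {
  named <- setNames(canonical_smiles,
                    sprintf("M%06d", seq_along(canonical_smiles)))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(named))
  ChemmineR::cid(sdf) <- names(named)
  obmols <- ChemmineR:::obmol(sdf)
  list(sdf = sdf, obmols = obmols)
}

# Count SMARTS matches (unique atom mappings) per molecule.
smarts_counts <- function(obmols, smarts) {
  as.integer(ChemmineOB::smartsSearch_OB(obmols, smarts, uniqueMatches = TRUE))
}

#' Identify n-alkanes
#'
#' An n-alkane is an unbranched acyclic saturated all-carbon hydrocarbon.
#' Its canonical SMILES is a plain run of `C` characters (no branches, ring
#' closures, heteroatoms or multiple bonds), which is tested directly.
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector; `NA` for unparseable SMILES.
#' @export
#' @examples
#' is_n_alkane(c("CCCCCC", "CC(C)CCC", "C1CCCCC1"))
is_n_alkane <- function(smiles) {
  can <- ob_canonical(smiles)
  ifelse(is.na(can), NA, grepl("^C+$", can))
}

#' SMILES token alphabet for the convolutional encoder
#'
#' The fixed token set used to one-hot encode canonical SMILES for the CNN:
#' two-character element tokens (`Cl`, `Br`, `Si`) are single tokens; all
#' other characters are their own token.
#'
#' @return A character vector of tokens.
#' @export
smiles_alphabet <- function() {
  c("C", "c", "N", "n", "O", "o", "S", "s", "P", "p", "F", "Cl", "Br", "I",
    "Si", "B", "H", "(", ")", "[", "]", "=", "#", "-", "+", "/", "\\", "@",
    ".", "%", "0", "1", "2", "3", "4", "5", "6", "7", "8", "9")
}

# Tokenize SMILES into alphabet indices; unknown characters are an error.
tokenize_smiles <- function(smiles, alphabet = smiles_alphabet()) {
  lapply(smiles, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    toks <- character(0)
    i <- 1
    while (i <= length(chars)) {
      pair <- if (i < length(chars)) paste0(chars[i], chars[i + 1]) else ""
      if (pair %in% c("Cl", "Br", "Si")) {
        toks <- c(toks, pair); i <- i + 2
      } else {
        toks <- c(toks, chars[i]); i <- i + 1
      }
    }
    idx <- match(toks, alphabet)
    if (anyNA(idx)) {
      abort(sprintf("SMILES '%s' contains token(s) outside the encoder alphabet: %s",
                    s, paste(unique(toks[is.na(idx)]), collapse = " ")))
    }
    idx
  })
}

#' One-hot structure encoding of a canonical SMILES for the CNN
#'
#' Encodes one molecule as a character-level one-hot grid over the token
#' alphabet: one column per SMILES position up to `L_max`, padding columns
#' all zero. Molecules whose canonical SMILES exceeds `L_max` tokens are
#' rejected.
#'
#' @param smiles A single SMILES string (canonicalized internally).
#' @param L_max Maximum token length of the grid.
#' @param alphabet Token alphabet (default [smiles_alphabet()]).
#' @return A numeric matrix with `length(alphabet)` rows and `L_max`
#'   columns; attribute `tokens` holds the token index vector.
#' @export
#' @examples
#' g <- cnn_encode("CCO", L_max = 10)
#' colSums(g)  # 3 occupied columns, 7 zero-padding columns
cnn_encode <- function(smiles, L_max = 150, alphabet = smiles_alphabet()) {
  stopifnot(length(smiles) == 1)
  can <- ob_canonical(smiles)
  if (is.na(can)) abort(sprintf("cannot parse SMILES '%s'", smiles))
  idx <- tokenize_smiles(can, alphabet)[[1]]
  if (length(idx) > L_max) {
    abort(sprintf("canonical SMILES has %d tokens, exceeding L_max = %d",
                  length(idx), L_max))
  }
  grid <- matrix(0, nrow = length(alphabet), ncol = L_max,
                 dimnames = list(alphabet, NULL))
  grid[cbind(idx, seq_along(idx))] <- 1
  attr(grid, "tokens") <- idx
  attr(grid, "canonical_smiles") <- can
  grid
}

# Decode a one-hot grid back to the SMILES string (round-trip oracle).
cnn_decode <- function(grid, alphabet = smiles_alphabet()) {
  occ <- colSums(grid) > 0
  paste(alphabet[apply(grid[, occ, drop = FALSE], 2, which.max)], collapse = "")
}
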