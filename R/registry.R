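#' Stationary-phase registries and fixed-length phase encoding
#'
#' A phase registry is the ordered catalog of stationary-phase types the
#' models know about: 36 non-polar phase types and 21 polar types (20 named
#' polyethylene-glycol-class phases plus the catch-all "Other polar").
#' Every neural model consumes the same 38-slot encoding array; non-polar
#' models use one-hot positions over the 36 non-polar slots, polar models
#' over the 21 polar slots, and the remaining slots are fixed at zero. The
#' shared array length is what makes non-polar to polar transfer learning a
#' pure weight copy.
#'
#' @param path Path to a registry CSV with columns `slot`, `family`, `phase`.
#'   Defaults to the registry shipped with the package.
#' @return An object of class `phase_registry`: a list with character vectors
#'   `nonpolar_types` (36), `polar_types` (21, last = "Other polar"), the
#'   `encoding_length` (38) and the source `version` tag.
#' @export
#' @examples
#' reg <- default_phase_registry()
#' length(reg$polar_types)
read_phase_registry <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_cols(df, c("slot", "family", "phase"), "phase registry")
  np <- df$phase[df$family == "non-polar"][order(df$slot[df$family == "non-polar"])]
  po <- df$phase[df$family == "polar"][order(df$slot[df$family == "polar"])]
  if (length(np) != 36) abort("registry must define exactly 36 non-polar phase types")
  if (length(po) != 21) abort("registry must define exactly 21 polar phase types")
  if (anyDuplicated(np) || anyDuplicated(po)) {
    abort("phase names must be unique within a registry family")
  }
  if (po[21] != "Other polar") abort("the last polar slot must be 'Other polar'")
  structure(list(nonpolar_types = np, polar_types = po, encoding_length = 38L,
                 version = basename(path)),
            class = "phase_registry")
}

#' @rdname read_phase_registry
#' @export
default_phase_registry <- function() {
  cache_get("default_registry", {
    read_phase_registry(system.file("extdata", "phase_registry_v1.csv",
                                    package = "ristack", mustWork = TRUE))
  })
}

#' @export
print.phase_registry <- function(x, ...) {
  cat(sprintf("<phase_registry %s> %d non-polar + %d polar types, encoding length %d\n",
              x$version, length(x$nonpolar_types), length(x$polar_types),
              x$encoding_length))
  invisible(x)
}

#' Encode stationary phases as fixed-length one-hot arrays
#'
#' Maps phase names to the shared 38-slot encoding. Polar phases are one-hot
#' over the 21 polar slots; a polar phase name absent from the registry maps
#' to the "Other polar" slot. Non-polar phases are one-hot over the 36
#' non-polar slots and the non-polar catalog is closed: an unknown name is an
#' error.
#'
#' @param phase Character vector of phase names.
#' @param family `"non-polar"` or `"polar"` (scalar or vector).
#' @param registry A [default_phase_registry()]-style registry.
#' @return A numeric matrix with `length(phase)` rows and 38 columns; each
#'   row sums to 1.
#' @export
#' @examples
#' rowSums(sp_encode("DB-WAX", "polar"))
#' sp_encode("some obscure PEG variant", "polar")[, 21]  # "Other polar" slot
sp_encode <- function(phase, family, registry = default_phase_registry()) {
  stopifnot(inherits(registry, "phase_registry"))
  family <- rep_len(family, length(phase))
  if (!all(family %in% c("non-polar", "polar"))) {
    abort("family must be 'non-polar' or 'polar' (mid-polar phases are not encoded)")
  }
  enc <- matrix(0, nrow = length(phase), ncol = registry$encoding_length)
  idx <- integer(length(phase))
  for (i in seq_along(phase)) {
    if (family[i] == "polar") {
      j <- match(phase[i], registry$polar_types)
      if (is.na(j)) j <- match("Other polar", registry$polar_types)
    } else {
      j <- match(phase[i], registry$nonpolar_types)
      if (is.na(j)) {
        abort(sprintf("unknown non-polar phase '%s' (the non-polar registry is closed)",
                      phase[i]))
      }
    }
    idx[i] <- j
    enc[i, j] <- 1
  }
  attr(enc, "active_index") <- idx
  attr(enc, "family") <- family
  enc
}

# internal package-level cache for expensive fixed artifacts
.ristack_cache <- new.env(parent = emptyenv())
cache_get <- function(key, expr) {
  if (!exists(key, envir = .ristack_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .ristack_cache)
  }
  get(key, envir = .ristack_cache, inherits = FALSE)
}
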