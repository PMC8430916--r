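#' Default stationary-phase set for the GC simulator
#'
#' Returns the simulator's built-in catalog of ten stationary phases with
#' Abraham solvation-equation parameters `(c, e, s, a, b, l)`: five non-polar
#' columns (squalane- and polydimethylsiloxane-like), four polar
#' (polyethylene-glycol-like) columns and one mid-polar column (DB-624-like,
#' cyanopropylphenyl/dimethyl polysiloxane). The parameter values are
#' plausible for isothermal GC but are not calibrated against measured
#' solvation data; they are chosen so that polar phases carry large `s` and
#' `a` coefficients (dipolarity and hydrogen-bond basicity of the phase) and
#' all phases retain more strongly with increasing analyte size (`l > 0`).
#'
#' @param ri_noise_sd Per-record Gaussian noise added to simulated retention
#'   indices, in index units. A single value recycled over phases.
#' @return A tibble with columns `phase`, `family`, `c`, `e`, `s`, `a`, `b`,
#'   `l`, `ri_noise_sd`.
#' @export
#' @examples
#' sim_default_phases()
sim_default_phases <- function(ri_noise_sd = 10) {
  tibble::tribble(
    ~phase,          ~family,      ~c,     ~e,    ~s,    ~a,    ~b,    ~l,
    "Squalane",      "non-polar", -0.300,  0.120, 0.000, 0.000, 0.000, 0.580,
    "DB-1",          "non-polar", -0.280,  0.100, 0.080, 0.050, 0.000, 0.570,
    "DB-5",          "non-polar", -0.290,  0.110, 0.150, 0.080, 0.000, 0.565,
    "OV-101",        "non-polar", -0.270,  0.090, 0.090, 0.060, 0.000, 0.572,
    "SE-54",         "non-polar", -0.285,  0.105, 0.160, 0.090, 0.000, 0.563,
    "DB-WAX",        "polar",     -0.550,  0.250, 1.300, 1.850, 0.000, 0.445,
    "Carbowax 20M",  "polar",     -0.540,  0.240, 1.280, 1.800, 0.000, 0.448,
    "FFAP",          "polar",     -0.570,  0.220, 1.350, 2.000, 0.100, 0.440,
    "HP-Innowax",    "polar",     -0.550,  0.260, 1.320, 1.880, 0.020, 0.444,
    "DB-624",        "mid-polar", -0.400,  0.100, 0.660, 0.470, 0.000, 0.520
  ) |>
    dplyr::mutate(ri_noise_sd = ri_noise_sd)
}

# Abraham L of the n-alkane with n carbons: affine in n, so the ladder of
# log k values is exactly affine on every phase and the Kovats index is an
# affine function of log k within the ladder span.
alkane_L <- function(n) 0.5 * n + 0.2

# family -> structural group summary used by the parameter map
sim_family_table <- function() {
  tibble::tribble(
    ~chem_class,      ~weight,
    "alcohol",        10,
    "diol",            3,
    "ester",          10,
    "ketone",          8,
    "aldehyde",        6,
    "ether",           6,
    "alkylbenzene",    8,
    "phenol",          4,
    "chloroalkane",    5,
    "bromoalkane",     4,
    "nitrile",         4,
    "amine",           4,
    "thiol",           3,
    "thioether",       3,
    "alkene",          6,
    "chloroalkene",    3,
    "cycloalkane",     5,
    "branched_alkane", 6,
    "acid",            4,
    "pyridine",        3,
    "furan",           3,
    "naphthalene",     2
  )
}

alk <- function(m) strrep("C", m)

# Number of positional variants available for a class at chain budget m.
sim_variant_max <- function(chem_class, m) {
  switch(chem_class,
    alcohol = ,
    chloroalkane = ,
    bromoalkane = max(1, (m + 1) %/% 2),
    ester = max(1, m - 1),
    ketone = ,
    ether = ,
    amine = ,
    thioether = ,
    alkene = ,
    branched_alkane = max(1, m %/% 2),
    alkylbenzene = 1 + m %/% 2,
    phenol = 3,
    1
  )
}

# Build one analyte of a class with chain budget m and positional variant v;
# returns the SMILES and exact structural counts for the parameter map.
sim_build_analyte <- function(chem_class, m, v = 1) {
  z <- list(smiles = NULL, nC = 0, nO = 0, nN = 0, nS = 0, nCl = 0, nBr = 0,
            oh = 0, phenol_oh = 0, acid = 0, ester = 0, ketone = 0,
            aldehyde = 0, ether = 0, nitrile = 0, amine = 0, thiol = 0,
            thioether = 0, aromatic = 0, cc_double = 0, ring = 0,
            pyridine = 0, furan = 0)
  m <- max(m, 2)
  v <- min(max(v, 1), sim_variant_max(chem_class, m))
  split2 <- function(v) c(v, m - v)  # interior split, both parts >= 1
  switch(chem_class,
    alcohol = {
      z$smiles <- if (v == 1) paste0(alk(m), "O") else
        paste0(alk(v - 1), "C(O)", alk(m - v))
      z$nC <- m; z$nO <- 1; z$oh <- 1
    },
    diol = {
      z$smiles <- paste0("OC", alk(m - 2), "CO")
      z$nC <- m; z$nO <- 2; z$oh <- 2
    },
    ester = {
      ab <- split2(v)
      z$smiles <- paste0(alk(ab[1]), "C(=O)O", alk(ab[2]))
      z$nC <- m + 1; z$nO <- 2; z$ester <- 1
    },
    ketone = {
      ab <- split2(v)
      z$smiles <- paste0(alk(ab[1]), "C(=O)", alk(ab[2]))
      z$nC <- m + 1; z$nO <- 1; z$ketone <- 1
    },
    aldehyde = {
      z$smiles <- paste0(alk(m), "C=O")
      z$nC <- m + 1; z$nO <- 1; z$aldehyde <- 1
    },
    ether = {
      ab <- split2(v)
      z$smiles <- paste0(alk(ab[1]), "O", alk(ab[2]))
      z$nC <- m; z$nO <- 1; z$ether <- 1
    },
    alkylbenzene = {
      if (v == 1) {
        z$smiles <- paste0(alk(m), "c1ccccc1")
      } else {
        a <- v - 1; b <- max(1, m - a)
        z$smiles <- paste0(alk(a), "c1ccc(", alk(b), ")cc1")
      }
      z$nC <- m + 6; z$aromatic <- 1; z$ring <- 1
    },
    phenol = {
      z$smiles <- switch(v,
        paste0("Oc1ccc(", alk(m), ")cc1"),
        paste0("Oc1cccc(", alk(m), ")c1"),
        paste0("Oc1ccccc1", alk(m)))
      z$nC <- m + 6; z$nO <- 1; z$phenol_oh <- 1; z$aromatic <- 1; z$ring <- 1
    },
    chloroalkane = {
      z$smiles <- if (v == 1) paste0(alk(m), "Cl") else
        paste0(alk(v - 1), "C(Cl)", alk(m - v))
      z$nC <- m; z$nCl <- 1
    },
    bromoalkane = {
      z$smiles <- if (v == 1) paste0(alk(m), "Br") else
        paste0(alk(v - 1), "C(Br)", alk(m - v))
      z$nC <- m; z$nBr <- 1
    },
    nitrile = {
      z$smiles <- paste0(alk(m), "C#N")
      z$nC <- m + 1; z$nN <- 1; z$nitrile <- 1
    },
    amine = {
      z$smiles <- if (v == 1) paste0(alk(m), "N") else
        paste0(alk(v), "N", alk(m - v))
      z$nC <- m; z$nN <- 1; z$amine <- 1
    },
    thiol = {
      z$smiles <- paste0(alk(m), "S")
      z$nC <- m; z$nS <- 1; z$thiol <- 1
    },
    thioether = {
      ab <- split2(v)
      z$smiles <- paste0(alk(ab[1]), "S", alk(ab[2]))
      z$nC <- m; z$nS <- 1; z$thioether <- 1
    },
    alkene = {
      ab <- split2(v)
      z$smiles <- paste0(alk(ab[1]), "C=C", alk(ab[2]))
      z$nC <- m + 2; z$cc_double <- 1
    },
    chloroalkene = {
      z$smiles <- paste0(alk(m), "C=CCl")
      z$nC <- m + 2; z$nCl <- 1; z$cc_double <- 1
    },
    cycloalkane = {
      z$smiles <- paste0(alk(m), "C1CCCCC1")
      z$nC <- m + 6; z$ring <- 1
    },
    branched_alkane = {
      z$smiles <- paste0(alk(v), "C(C)", alk(m - v))
      z$nC <- m + 2
    },
    acid = {
      z$smiles <- paste0(alk(m), "C(=O)O")
      z$nC <- m + 1; z$nO <- 2; z$acid <- 1
    },
    pyridine = {
      z$smiles <- paste0(alk(m), "c1ccncc1")
      z$nC <- m + 5; z$nN <- 1; z$aromatic <- 1; z$ring <- 1; z$pyridine <- 1
    },
    furan = {
      z$smiles <- paste0(alk(m), "c1ccco1")
      z$nC <- m + 4; z$nO <- 1; z$aromatic <- 1; z$ring <- 1; z$furan <- 1
    },
    naphthalene = {
      z$smiles <- paste0(alk(m), "c1ccc2ccccc2c1")
      z$nC <- m + 10; z$aromatic <- 2; z$ring <- 2
    },
    abort(paste("unknown analyte class:", chem_class))
  )
  z$n_heavy <- z$nC + z$nO + z$nN + z$nS + z$nCl + z$nBr
  z
}

# Map structural counts to Abraham analyte parameters. Deterministic apart
# from the explicitly passed jitter values; donor acidity A is exactly zero
# when no donor group is present.
sim_abraham_params <- function(z, jit) {
  donors <- z$oh + z$phenol_oh + z$acid + z$amine + z$thiol
  E <- 0.60 * z$aromatic + 0.20 * z$nCl + 0.35 * z$nBr + 0.10 * z$cc_double +
    0.10 * (z$ketone + z$aldehyde + z$ester + z$acid) + 0.30 * z$nS +
    max(jit[1], 0) * 0.5
  S <- 0.42 * z$oh + 0.75 * z$phenol_oh + 0.65 * (z$ketone + z$aldehyde) +
    0.55 * z$ester + 0.25 * z$ether + 0.90 * z$nitrile + 0.65 * z$acid +
    0.50 * z$aromatic + 0.35 * z$nCl + 0.40 * z$nBr + 0.35 * z$amine +
    0.35 * (z$thiol + z$thioether) + 0.08 * z$cc_double + abs(jit[2]) * 0.3
  A <- if (donors == 0) 0 else {
    0.37 * z$oh + 0.60 * z$phenol_oh + 0.60 * z$acid + 0.16 * z$amine +
      0.05 * z$thiol + abs(jit[3]) * 0.1
  }
  B <- 0.48 * z$oh + 0.30 * z$phenol_oh + 0.45 * z$ether + 0.45 * z$ester +
    0.51 * z$ketone + 0.45 * z$aldehyde + 0.45 * z$acid + 0.33 * z$nitrile +
    0.61 * z$amine + 0.52 * z$pyridine + 0.13 * z$furan +
    0.24 * (z$thiol + z$thioether) + 0.14 * z$aromatic + 0.10 * z$nCl +
    0.12 * z$nBr + abs(jit[4]) * 0.2
  L <- 0.50 * z$n_heavy + 0.30 * z$aromatic + 0.25 * z$oh +
    0.35 * z$phenol_oh + 0.20 * (z$ketone + z$aldehyde) + 0.35 * z$ester +
    0.50 * z$acid + 0.05 * z$ether + 0.30 * z$nitrile + 0.20 * z$amine +
    0.40 * (z$thiol + z$thioether) + 0.25 * z$nCl + 0.45 * z$nBr +
    jit[5] * 0.05
  L <- min(max(L, 1.0), 19.5)
  c(E = E, S = S, A = A, B = B, L = L)
}

#' Generate a synthetic analyte library with Abraham solute parameters
#'
#' Draws `n` distinct organic analytes across 21 compound classes
#' (alcohols, diols, esters, ketones, aldehydes, ethers, alkylbenzenes,
#' phenols, halides, nitriles, amines, sulfur compounds, alkenes,
#' cycloalkanes, branched alkanes, acids and aromatic heterocycles) with
#' chain lengths spanning roughly C2-C28, and assigns each a set of Abraham
#' solute parameters `(E, S, A, B, L)` linked to its structure: the size
#' parameter `L` grows with heavy-atom count (so homologs elute in order),
#' the hydrogen-bond acidity `A` counts donor groups and is exactly zero for
#' donor-free analytes, and `S`/`B` reflect polar functional groups. Small
#' seeded jitter makes analytes of the same class non-degenerate.
#' n-Alkanes are never generated: they are reserved for the reference ladder.
#'
#' @param n Number of distinct analytes.
#' @param seed Integer seed; the library is byte-identical for a given
#'   `(n, seed)`.
#' @return A tibble with columns `analyte_id`, `smiles`, `chem_class`,
#'   `n_heavy`, `E`, `S`, `A`, `B`, `L`.
#' @export
#' @examples
#' lib <- generate_library(20, seed = 1)
#' head(lib)
generate_library <- function(n, seed = 1) {
  stopifnot(n >= 1)
  fam <- sim_family_table()
  with_seed_(derive_seed(seed, "library"), {
    out <- vector("list", 0)
    seen <- new.env(parent = emptyenv())
    add_one <- function(chem_class, m, v) {
      z <- sim_build_analyte(chem_class, m, v)
      if (exists(z$smiles, envir = seen, inherits = FALSE)) return(FALSE)
      assign(z$smiles, TRUE, envir = seen)
      p <- sim_abraham_params(z, rnorm(5))
      out[[length(out) + 1]] <<- tibble(
        smiles = z$smiles, chem_class = chem_class, n_heavy = z$n_heavy,
        E = p[["E"]], S = p[["S"]], A = p[["A"]], B = p[["B"]], L = p[["L"]]
      )
      TRUE
    }
    guard <- 0
    while (length(out) < n && guard < 40) {
      guard <- guard + 1
      n_draw <- max(2 * (n - length(out)), 20)
      classes <- sample(fam$chem_class, n_draw, replace = TRUE, prob = fam$weight)
      sizes <- pmax(2, pmin(28, 2 + stats::rgeom(n_draw, prob = 0.11)))
      for (i in seq_len(n_draw)) {
        v <- sample.int(sim_variant_max(classes[i], sizes[i]), 1)
        add_one(classes[i], sizes[i], v)
        if (length(out) >= n) break
      }
    }
    if (length(out) < n) {
      # deterministic completion: sweep the full template space in seeded
      # random order until the requested count is reached
      grid <- dplyr::bind_rows(lapply(fam$chem_class, function(cl) {
        dplyr::bind_rows(lapply(2:28, function(m) {
          tibble(chem_class = cl, m = m, v = seq_len(sim_variant_max(cl, m)))
        }))
      }))
      grid <- grid[sample.int(nrow(grid)), ]
      for (i in seq_len(nrow(grid))) {
        if (length(out) >= n) break
        add_one(grid$chem_class[i], grid$m[i], grid$v[i])
      }
    }
    if (length(out) < n) {
      abort(sprintf(
        "the analyte template space holds %d distinct structures; requested %d",
        length(out), n))
    }
    dplyr::bind_rows(out) |>
      dplyr::mutate(analyte_id = sprintf("A%05d", dplyr::row_number()),
                    .before = 1)
  })
}

#' Abraham solvation-equation retention factors
#'
#' Computes `log k = c + eE + sS + aA + bB + lL` for every (analyte, phase)
#' pair: the linear solvation energy relationship that drives the simulator.
#'
#' @param analytes Tibble with columns `analyte_id`, `E`, `S`, `A`, `B`, `L`
#'   (as produced by [generate_library()]).
#' @param phases Tibble with columns `phase`, `c`, `e`, `s`, `a`, `b`, `l`
#'   (as produced by [sim_default_phases()]).
#' @return A tibble `analyte_id`, `phase`, `log_k`.
#' @export
abraham_log_k <- function(analytes, phases) {
  assert_cols(analytes, c("analyte_id", "E", "S", "A", "B", "L"))
  assert_cols(phases, c("phase", "c", "e", "s", "a", "b", "l"))
  tidyr::crossing(analyte_id = analytes$analyte_id, phase = phases$phase) |>
    dplyr::left_join(analytes, by = "analyte_id") |>
    dplyr::left_join(phases, by = "phase") |>
    dplyr::mutate(log_k = .data$c + .data$e * .data$E + .data$s * .data$S +
                    .data$a * .data$A + .data$b * .data$B + .data$l * .data$L) |>
    dplyr::select("analyte_id", "phase", "log_k")
}

#' n-Alkane reference ladder for the simulated phases
#'
#' Builds the per-phase `log k` values of the n-alkane homolog series used to
#' anchor the Kovats index. Alkane solute parameters are `E = S = A = B = 0`
#' and `L` affine in carbon number, so each ladder is strictly increasing
#' whenever the phase's `l` coefficient is positive.
#'
#' @param phases Phase tibble (see [sim_default_phases()]).
#' @param n_range Integer carbon-number range `c(min, max)` of the ladder.
#' @return A tibble `phase`, `n_carbon`, `log_k`.
#' @export
alkane_ladder <- function(phases, n_range = c(4, 40)) {
  assert_cols(phases, c("phase", "c", "l"))
  stopifnot(length(n_range) == 2, n_range[1] < n_range[2])
  tidyr::crossing(phase = phases$phase,
                  n_carbon = seq(n_range[1], n_range[2])) |>
    dplyr::left_join(dplyr::select(phases, "phase", "c", "l"), by = "phase") |>
    dplyr::mutate(log_k = .data$c + .data$l * alkane_L(.data$n_carbon)) |>
    dplyr::select("phase", "n_carbon", "log_k")
}

#' Kovats retention index by n-alkane bracketing
#'
#' Converts `log k` values on one phase into Kovats retention indices using
#' `RI = 100 * (n + (log k - log k_n) / (log k_(n+1) - log k_n))` where `n`
#' indexes the bracketing n-alkanes. Values outside the ladder are linearly
#' extrapolated with the nearest alkane pair and flagged.
#'
#' @param log_k Numeric vector of retention factors (log10 scale is
#'   irrelevant as long as ladder and analytes use the same base).
#' @param ladder Tibble with columns `n_carbon`, `log_k` for a single phase,
#'   strictly increasing in `log_k`.
#' @return A tibble with columns `ri` and `extrapolated`.
#' @export
#' @examples
#' ph <- sim_default_phases()[1, ]
#' lad <- dplyr::filter(alkane_ladder(ph), phase == ph$phase)
#' kovats_ri(lad$log_k[5], lad)   # the C8 ladder member itself -> 800
kovats_ri <- function(log_k, ladder) {
  assert_cols(ladder, c("n_carbon", "log_k"))
  ladder <- dplyr::arrange(ladder, .data$n_carbon)
  lk <- ladder$log_k
  nn <- ladder$n_carbon
  if (any(diff(lk) <= 0)) {
    abort("alkane ladder must be strictly increasing in log k on this phase")
  }
  i <- findInterval(log_k, lk)
  extrap <- i < 1 | i >= length(lk)
  i <- pmin(pmax(i, 1L), length(lk) - 1L)
  ri <- 100 * (nn[i] + (log_k - lk[i]) / (lk[i + 1] - lk[i]))
  tibble(ri = ri, extrapolated = extrap)
}

#' Construct a phase as a linear combination of existing phases
#'
#' If the solvation equation holds exactly, `log k` on a phase whose
#' parameter vector `(c, e, s, a, b, l)` is a weighted sum of other phases'
#' vectors equals the same weighted sum of their `log k` values. Such a phase
#' provides exact ground truth for recovery tests of the greedy
#' phase-combination builder.
#'
#' @param phases Phase tibble holding the base phases (at most five rows).
#' @param weights Numeric weights, one per row of `phases`.
#' @param name Name of the new phase.
#' @param family Phase family label for the new phase.
#' @param ri_noise_sd Per-record RI noise of the new phase, index units.
#' @return A one-row phase tibble.
#' @export
make_linear_phase <- function(phases, weights, name,
                              family = "mid-polar", ri_noise_sd = 0) {
  assert_cols(phases, c("phase", "c", "e", "s", "a", "b", "l"))
  if (nrow(phases) == 0) abort("at least one base phase is required")
  if (nrow(phases) > 5) abort("at most five base phases are supported")
  stopifnot(length(weights) == nrow(phases), all(is.finite(weights)))
  v <- colSums(as.matrix(phases[, c("c", "e", "s", "a", "b", "l")]) * weights)
  tibble(phase = name, family = family, c = v[["c"]], e = v[["e"]],
         s = v[["s"]], a = v[["a"]], b = v[["b"]], l = v[["l"]],
         ri_noise_sd = ri_noise_sd)
}

#' Simulate a multi-phase retention corpus with known ground truth
#'
#' Crosses an analyte library with a phase set, computes noiseless Kovats
#' indices through the Abraham equation and the n-alkane ladder, then draws
#' `replicates` noisy retention records per (analyte, phase) to emulate the
#' replicate scatter of curated retention databases.
#'
#' @param library Analyte tibble from [generate_library()].
#' @param phases Phase tibble (default [sim_default_phases()]).
#' @param ladder Alkane ladder (default built from `phases`).
#' @param replicates Number of records per (analyte, phase).
#' @param seed Integer seed for the noise draws.
#' @return An object of class `ri_sim_corpus`: a list with `records`
#'   (tibble `smiles`, `phase`, `family`, `ri`, `source`, `analyte_id`),
#'   `truth` (noiseless RI per analyte and phase), plus the `analytes`,
#'   `phases` and `ladder` used.
#' @export
#' @examples
#' corp <- build_corpus(generate_library(30, seed = 1), seed = 2)
#' head(corp$records)
build_corpus <- function(library, phases = sim_default_phases(),
                         ladder = alkane_ladder(phases),
                         replicates = 1, seed = 1) {
  assert_cols(phases, c("phase", "family", "ri_noise_sd"))
  stopifnot(replicates >= 1)
  lk <- abraham_log_k(library, phases)
  truth <- lk |>
    dplyr::group_by(.data$phase) |>
    dplyr::group_modify(function(d, key) {
      lad <- dplyr::filter(ladder, .data$phase == key$phase)
      dplyr::bind_cols(d, kovats_ri(d$log_k, lad))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(ri_true = "ri") |>
    dplyr::left_join(dplyr::select(phases, "phase", "family"), by = "phase")
  records <- with_seed_(derive_seed(seed, "corpus-noise"), {
    truth |>
      dplyr::left_join(dplyr::select(phases, "phase", "ri_noise_sd"),
                       by = "phase") |>
      tidyr::uncount(replicates) |>
      dplyr::mutate(ri = .data$ri_true + rnorm(dplyr::n(), 0, .data$ri_noise_sd)) |>
      dplyr::left_join(dplyr::select(library, "analyte_id", "smiles"),
                       by = "analyte_id") |>
      dplyr::mutate(source = "simulator") |>
      dplyr::select("smiles", "phase", "family", "ri", "source", "analyte_id")
  })
  structure(list(records = records,
                 truth = dplyr::select(truth, "analyte_id", "phase", "family",
                                       "ri_true", "extrapolated"),
                 analytes = library, phases = phases, ladder = ladder),
            class = "ri_sim_corpus")
}

#' @export
print.ri_sim_corpus <- function(x, ...) {
  cat(sprintf("<ri_sim_corpus> %d records | %d analytes | %d phases (%s)\n",
              nrow(x$records), nrow(x$analytes), nrow(x$phases),
              paste(unique(x$phases$family), collapse = ", ")))
  invisible(x)
}
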