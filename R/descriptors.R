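#' @name descriptors
#' @title Molecular descriptor block
#'
#' @description
#' The feature set every model consumes is a fixed, versioned manifest of
#' 327 descriptors: 243 general molecular descriptors (OpenBabel
#' physicochemical properties, element counts, graph/topological indices,
#' topological-distance atom-pair counts and atom-environment SMARTS counts)
#' plus 84 functional-group counters defined by a shipped SMARTS pattern
#' table. Descriptors are scaled by per-descriptor affine factors that are
#' frozen in the manifest file and never refit on a training set.
NULL

std_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                 I = 1, Si = 4, H = 1)

pair_elements <- function() c("C", "N", "O", "S", "X")

# The 65 atom-environment SMARTS of the general descriptor block.
env_smarts_table <- function() {
  tibble::tribble(
    ~name, ~smarts,
    "env_C_sp3",          "[CX4]",
    "env_C_sp2",          "[CX3]",
    "env_C_sp",           "[CX2]",
    "env_CH3",            "[CX4H3]",
    "env_CH2",            "[CX4H2]",
    "env_CH1",            "[CX4H1]",
    "env_C_quart",        "[CX4H0]",
    "env_c_arom",         "[c]",
    "env_cH_arom",        "[cH]",
    "env_c_subst",        "[cH0]",
    "env_N_sp3",          "[NX3]",
    "env_N_sp2",          "[NX2]",
    "env_N_sp",           "[NX1]",
    "env_n_arom",         "[n]",
    "env_NH2",            "[NX3H2]",
    "env_NH1",            "[NX3H1]",
    "env_N_tert",         "[NX3H0]",
    "env_O_sp3",          "[OX2]",
    "env_O_sp2",          "[OX1]",
    "env_o_arom",         "[o]",
    "env_OH",             "[OX2H]",
    "env_O_noH",          "[OX2H0]",
    "env_S_sp3",          "[SX2]",
    "env_s_arom",         "[s]",
    "env_SH",             "[SX2H]",
    "env_S_hival",        "[#16X3,#16X4]",
    "env_F",              "[F]",
    "env_Cl",             "[Cl]",
    "env_Br",             "[Br]",
    "env_I",              "[I]",
    "env_halogen",        "[F,Cl,Br,I]",
    "env_C_O_single",     "[#6][OX2]",
    "env_C_O_double",     "[CX3]=[OX1]",
    "env_C_N_single",     "[#6][NX3]",
    "env_C_N_double",     "[#6]=[NX2]",
    "env_C_N_triple",     "[CX2]#[NX1]",
    "env_C_S_single",     "[#6][SX2]",
    "env_C_halogen",      "[#6][F,Cl,Br,I]",
    "env_aryl_halogen",   "[c][F,Cl,Br,I]",
    "env_cc_arom",        "cc",
    "env_cn_arom",        "cn",
    "env_co_arom",        "co",
    "env_cs_arom",        "cs",
    "env_aryl_alkyl",     "[c][CX4]",
    "env_aryl_O",         "[c][OX2]",
    "env_aryl_N",         "[c][NX3]",
    "env_ring3",          "[r3]",
    "env_ring4",          "[r4]",
    "env_ring5",          "[r5]",
    "env_ring6",          "[r6]",
    "env_ring7",          "[r7]",
    "env_ring8",          "[r8]",
    "env_ring_atom",      "[R]",
    "env_ring_fusion",    "[R2]",
    "env_biaryl_link",    "[R]-!@[R]",
    "env_alkene",         "[CX3]=[CX3]",
    "env_alkyne",         "[CX2]#[CX2]",
    "env_conjugated_CC",  "[CX3]=[CX3][CX3]=[CX3]",
    "env_vicinal_diol",   "[OX2H][#6][#6][OX2H]",
    "env_rotatable",      "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
    "env_amide_frame",    "[NX3][CX3]=[OX1]",
    "env_ester_frame",    "[OX2][CX3]=[OX1]",
    "env_acid_frame",     "[OX2H][CX3]=[OX1]",
    "env_hbond_donor",    "[OX2H,NX3H1,NX3H2,SX2H]",
    "env_hbond_acceptor", "[OX2,OX1,NX3,NX2,n,o]"
  )
}

# The 84 functional-group counter SMARTS (the shipped pattern table).
functional_group_table <- function() {
  tibble::tribble(
    ~name, ~smarts,
    "fg_hydroxyl",          "[OX2H]",
    "fg_primary_alcohol",   "[CX4H2][OX2H]",
    "fg_secondary_alcohol", "[CX4H1]([#6])[OX2H]",
    "fg_tertiary_alcohol",  "[CX4H0]([#6])([#6])[OX2H]",
    "fg_phenol",            "[c][OX2H]",
    "fg_enol",              "[OX2H][#6X3]=[#6]",
    "fg_ether_aliphatic",   "[CX4][OX2][CX4]",
    "fg_ether_aromatic",    "[c][OX2][CX4]",
    "fg_diaryl_ether",      "[c][OX2][c]",
    "fg_methoxy",           "[OX2][CH3]",
    "fg_epoxide",           "[OX2r3]",
    "fg_peroxide",          "[OX2][OX2]",
    "fg_aldehyde",          "[CX3H1]=[OX1]",
    "fg_ketone",            "[#6][CX3](=[OX1])[#6]",
    "fg_aryl_ketone",       "[c][CX3](=[OX1])[#6]",
    "fg_carboxylic_acid",   "[CX3](=[OX1])[OX2H]",
    "fg_ester",             "[CX3](=[OX1])[OX2][#6]",
    "fg_formate",           "[CX3H1](=[OX1])[OX2][#6]",
    "fg_acetate",           "[CH3][CX3](=[OX1])[OX2]",
    "fg_lactone",           "[C;R](=[OX1])[O;R]",
    "fg_carbonate",         "[OX2][CX3](=[OX1])[OX2]",
    "fg_anhydride",         "[CX3](=[OX1])[OX2][CX3]=[OX1]",
    "fg_carbonyl_any",      "[CX3]=[OX1]",
    "fg_primary_amine",     "[NX3H2][CX4]",
    "fg_secondary_amine",   "[NX3H1]([CX4])[CX4]",
    "fg_tertiary_amine",    "[NX3H0]([CX4])([CX4])[CX4]",
    "fg_aromatic_amine",    "[NX3H2][c]",
    "fg_amide",             "[CX3](=[OX1])[NX3]",
    "fg_primary_amide",     "[CX3](=[OX1])[NX3H2]",
    "fg_lactam",            "[C;R](=[OX1])[N;R]",
    "fg_nitrile",           "[CX2]#[NX1]",
    "fg_nitro",             "[NX3](~[OX1])~[OX1]",
    "fg_imine",             "[CX3]=[NX2]",
    "fg_oxime",             "[CX3]=[NX2][OX2H]",
    "fg_hydrazine",         "[NX3][NX3]",
    "fg_azo",               "[NX2]=[NX2]",
    "fg_isocyanate",        "[NX2]=[CX2]=[OX1]",
    "fg_urea",              "[NX3][CX3](=[OX1])[NX3]",
    "fg_carbamate",         "[NX3][CX3](=[OX1])[OX2]",
    "fg_nitrate_ester",     "[OX2][NX3](~[OX1])~[OX1]",
    "fg_pyridine_N",        "[nX2]",
    "fg_pyrrole_NH",        "[nH]",
    "fg_thiol",             "[SX2H]",
    "fg_thioether",         "[#6][SX2][#6]",
    "fg_disulfide",         "[SX2][SX2]",
    "fg_thiophene_S",       "[sX2]",
    "fg_sulfoxide",         "[SX3]=[OX1]",
    "fg_sulfone",           "[SX4](=[OX1])=[OX1]",
    "fg_sulfonate",         "[SX4](=[OX1])(=[OX1])[OX2]",
    "fg_thiocarbonyl",      "[CX3]=[SX1]",
    "fg_fluoro_aliphatic",  "[CX4][F]",
    "fg_fluoro_aromatic",   "[c][F]",
    "fg_chloro_aliphatic",  "[CX4][Cl]",
    "fg_chloro_aromatic",   "[c][Cl]",
    "fg_chloro_vinyl",      "[CX3]=[CX3][Cl]",
    "fg_bromo_aliphatic",   "[CX4][Br]",
    "fg_bromo_aromatic",    "[c][Br]",
    "fg_iodo",              "[#6][I]",
    "fg_CF3",               "[CX4]([F])([F])[F]",
    "fg_CCl3",              "[CX4]([Cl])([Cl])[Cl]",
    "fg_gem_dihalide",      "[CX4]([F,Cl,Br,I])[F,Cl,Br,I]",
    "fg_methyl",            "[CH3]",
    "fg_methylene",         "[CH2]",
    "fg_methine",           "[CX4H1]",
    "fg_quaternary_C",      "[CX4H0]",
    "fg_vinyl",             "[CX3H2]=[CX3]",
    "fg_internal_alkene",   "[CX3H1]=[CX3H1]",
    "fg_alkyne_terminal",   "[CX2H1]#[CX2]",
    "fg_alkyne_internal",   "[CX2H0]#[CX2H0]",
    "fg_allene",            "[CX3]=[CX2]=[CX3]",
    "fg_aromatic_C",        "[c]",
    "fg_aromatic_CH",       "[cH]",
    "fg_benzene_ring",      "c1ccccc1",
    "fg_fused_aromatic",    "[cR2]",
    "fg_cyclopropane",      "[CX4r3]",
    "fg_cyclobutane",       "[CX4r4]",
    "fg_cyclopentane",      "[CX4r5]",
    "fg_cyclohexane",       "[CX4r6]",
    "fg_ring_alkyl",        "[CR]",
    "fg_silicon",           "[Si]",
    "fg_phosphorus",        "[P]",
    "fg_phosphoryl",        "[PX4]=[OX1]",
    "fg_conjugated_diene",  "[CX3]=[CX3][CX3]=[CX3]",
    "fg_benzyl",            "[c][CX4H2]"
  )
}

graph_stat_names <- function() {
  c("n_heavy", "n_bonds", "n_rings", "n_single", "n_double_kek", "n_triple",
    "deg1", "deg2", "deg3", "deg4", "wiener", "diameter", "radius",
    "mean_dist", "petitjean", "zagreb1", "zagreb2", "randic",
    "walk2", "walk3", "walk4", "spect_radius", "frac_hetero", "frac_halogen")
}

# Full 327-row descriptor definition table (class + parameters, no scaling).
descriptor_definitions <- function() {
  ob <- tibble(name = paste0("ob_", c("HBA1", "HBA2", "HBD", "logP", "MR",
                                      "MW", "nF", "TPSA")),
               class = "ob_prop",
               p1 = c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA"),
               p2 = "", p3 = "")
  elem <- tibble(name = paste0("count_", names(std_valence)),
                 class = "element", p1 = names(std_valence), p2 = "", p3 = "")
  graph <- tibble(name = paste0("graph_", graph_stat_names()),
                  class = "graph", p1 = graph_stat_names(), p2 = "", p3 = "")
  pe <- pair_elements()
  prs <- expand.grid(j = seq_along(pe), i = seq_along(pe), d = 1:9) |>
    dplyr::filter(.data$i <= .data$j) |>
    dplyr::arrange(.data$d, .data$i, .data$j)
  pair <- tibble(name = sprintf("pair_%s_%s_d%d", pe[prs$i], pe[prs$j], prs$d),
                 class = "pair", p1 = pe[prs$i], p2 = pe[prs$j],
                 p3 = as.character(prs$d))
  env <- env_smarts_table() |>
    dplyr::transmute(name = .data$name, class = "smarts_env",
                     p1 = .data$smarts, p2 = "", p3 = "")
  fg <- functional_group_table() |>
    dplyr::transmute(name = .data$name, class = "fg_smarts",
                     p1 = .data$smarts, p2 = "", p3 = "")
  dplyr::bind_rows(ob, elem, graph, pair, env, fg)
}

#' @rdname descriptors
#' @param path Path to a descriptor manifest CSV (columns `name`, `class`,
#'   `p1`, `p2`, `p3`, `center`, `scale`).
#' @return `read_descriptor_manifest()` / `default_descriptor_manifest()`
#'   return a `descriptor_manifest` tibble of 327 rows (243 general + 84
#'   functional-group counters).
#' @export
read_descriptor_manifest <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c(p1 = "character", p2 = "character",
                                          p3 = "character")))
  assert_cols(df, c("name", "class", "p1", "p2", "p3", "center", "scale"),
              "descriptor manifest")
  n_gen <- sum(df$class != "fg_smarts")
  if (n_gen != 243 || sum(df$class == "fg_smarts") != 84) {
    abort(sprintf(
      "descriptor manifest must hold 243 general + 84 functional-group rows, got %d + %d",
      n_gen, sum(df$class == "fg_smarts")))
  }
  if (any(!is.finite(df$scale)) || any(df$scale == 0)) {
    abort("descriptor scales must be finite and non-zero")
  }
  attr(df, "version") <- basename(path)
  class(df) <- c("descriptor_manifest", class(df))
  df
}

#' @rdname descriptors
#' @export
default_descriptor_manifest <- function() {
  cache_get("default_manifest", {
    read_descriptor_manifest(system.file("extdata", "descriptor_manifest_v1.csv",
                                         package = "ristack", mustWork = TRUE))
  })
}

# ---- raw descriptor computation ------------------------------------------

elements_of <- function(sdf1) {
  sub("_.*$", "", rownames(ChemmineR::atomblock(sdf1)))
}

# Graph-derived raw features for one molecule: element counts, graph stats
# and topological atom-pair counts, as a named numeric vector.
graph_features_one <- function(sdf1, pair_names) {
  elems <- elements_of(sdf1)
  n <- length(elems)
  bb <- ChemmineR::bondblock(sdf1)
  e1 <- if (nrow(bb)) as.integer(bb[, 1]) else integer(0)
  e2 <- if (nrow(bb)) as.integer(bb[, 2]) else integer(0)
  ord <- if (nrow(bb)) as.integer(bb[, 3]) else integer(0)

  ecount <- setNames(numeric(length(std_valence)),
                     paste0("count_", names(std_valence)))
  tab <- table(elems)
  known <- intersect(names(tab), names(std_valence))
  ecount[paste0("count_", known)] <- as.numeric(tab[known])
  val <- std_valence[elems]
  val[is.na(val)] <- 0
  bondsum <- numeric(n)
  for (k in seq_along(e1)) {
    bondsum[e1[k]] <- bondsum[e1[k]] + ord[k]
    bondsum[e2[k]] <- bondsum[e2[k]] + ord[k]
  }
  ecount["count_H"] <- sum(pmax(0, val - bondsum))

  deg <- numeric(n)
  for (k in seq_along(e1)) {
    deg[e1[k]] <- deg[e1[k]] + 1
    deg[e2[k]] <- deg[e2[k]] + 1
  }
  A <- matrix(0, n, n)
  if (length(e1)) {
    A[cbind(e1, e2)] <- 1
    A[cbind(e2, e1)] <- 1
  }
  if (n > 1 && length(e1)) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    D <- igraph::distances(g)
  } else {
    D <- matrix(0, n, n)
  }
  up <- upper.tri(D)
  dv <- D[up]
  dv_fin <- dv[is.finite(dv)]
  ecc <- if (n > 1) apply(ifelse(is.finite(D), D, 0), 1, max) else 0
  diam <- max(ecc)
  rad <- if (all(ecc == 0)) 0 else min(ecc[ecc >= 0])
  A2 <- A %*% A; A3 <- A2 %*% A; A4 <- A3 %*% A
  halogen <- c("F", "Cl", "Br", "I")
  gs <- c(
    n_heavy = n,
    n_bonds = length(e1),
    n_rings = length(e1) - n + 1,  # cyclomatic number (connected molecules)
    n_single = sum(ord == 1),
    n_double_kek = sum(ord == 2),
    n_triple = sum(ord == 3),
    deg1 = sum(deg == 1), deg2 = sum(deg == 2),
    deg3 = sum(deg == 3), deg4 = sum(deg >= 4),
    wiener = sum(dv_fin),
    diameter = diam,
    radius = rad,
    mean_dist = if (length(dv_fin)) mean(dv_fin) else 0,
    petitjean = if (rad > 0) (diam - rad) / rad else 0,
    zagreb1 = sum(deg^2),
    zagreb2 = if (length(e1)) sum(deg[e1] * deg[e2]) else 0,
    randic = if (length(e1)) sum(1 / sqrt(pmax(deg[e1] * deg[e2], 1))) else 0,
    walk2 = sum(A2), walk3 = sum(A3), walk4 = sum(A4),
    spect_radius = if (n > 1) max(eigen(A, symmetric = TRUE,
                                        only.values = TRUE)$values) else 0,
    frac_hetero = mean(elems != "C"),
    frac_halogen = mean(elems %in% halogen)
  )
  names(gs) <- paste0("graph_", names(gs))

  grp <- ifelse(elems %in% halogen, "X",
                ifelse(elems %in% pair_elements(), elems, NA))
  pc <- setNames(numeric(length(pair_names)), pair_names)
  if (n > 1) {
    ij <- which(up & is.finite(D) & D >= 1 & D <= 9, arr.ind = TRUE)
    if (nrow(ij)) {
      gi <- grp[ij[, 1]]; gj <- grp[ij[, 2]]
      keep <- !is.na(gi) & !is.na(gj)
      if (any(keep)) {
        a <- pmin(gi[keep], gj[keep]); b <- pmax(gi[keep], gj[keep])
        dd <- D[cbind(ij[keep, 1], ij[keep, 2])]
        key <- sprintf("pair_%s_%s_d%d", a, b, dd)
        kt <- table(key)
        hit <- intersect(names(kt), pair_names)
        pc[hit] <- as.numeric(kt[hit])
      }
    }
  }
  c(ecount, gs, pc)
}

#' @rdname descriptors
#' @param smiles Character vector of SMILES (canonicalized internally; all
#'   must be parseable).
#' @param manifest A descriptor manifest.
#' @param scaled Apply the manifest's frozen affine scaling factors
#'   (`(x - center) / scale`). The functional-group sub-block is integer
#'   counts when `scaled = FALSE`.
#' @return `descriptor_matrix()` returns a numeric matrix with one row per
#'   molecule and 327 named columns in manifest order; non-finite raw values
#'   are imputed with the descriptor's center (its configured default) and
#'   logged. Rows are cached per molecule, so repeated featurization of
#'   overlapping molecule sets is cheap.
#' @export
descriptor_matrix <- function(smiles, manifest = default_descriptor_manifest(),
                              scaled = TRUE) {
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    abort(sprintf("unparseable SMILES passed to descriptor_matrix: %s",
                  paste(head(smiles[is.na(can)], 3), collapse = " ")))
  }
  # per-molecule cache of raw descriptor rows, keyed by manifest version
  store_key <- paste0("rows_", attr(manifest, "version") %||% "adhoc")
  store <- .ristack_cache[[store_key]]
  if (is.null(store)) {
    store <- new.env(parent = emptyenv())
    .ristack_cache[[store_key]] <- store
  }
  todo <- unique(can[!vapply(can, exists, logical(1), envir = store,
                             inherits = FALSE)])
  if (length(todo) > 0) {
    raw <- descriptor_matrix_raw(todo, manifest)
    for (i in seq_along(todo)) assign(todo[i], raw[i, ], envir = store)
  }
  out <- do.call(rbind, lapply(can, get, envir = store, inherits = FALSE))
  dimnames(out) <- list(NULL, manifest$name)
  if (scaled) {
    out <- sweep(sweep(out, 2, manifest$center, "-"), 2, manifest$scale, "/")
  }
  attr(out, "manifest_version") <- attr(manifest, "version")
  out
}

descriptor_matrix_raw <- function(can, manifest) {
  h <- mol_handles(can)
  n <- length(can)
  out <- matrix(NA_real_, nrow = n, ncol = nrow(manifest),
                dimnames = list(NULL, manifest$name))

  ob_rows <- manifest$class == "ob_prop"
  if (any(ob_rows)) {
    pr <- ChemmineR::propOB(h$sdf)
    for (j in which(ob_rows)) {
      col <- manifest$p1[j]
      out[, j] <- if (col %in% names(pr)) as.numeric(pr[[col]]) else NA_real_
    }
  }

  pair_names <- manifest$name[manifest$class == "pair"]
  feat_cols <- manifest$name[manifest$class %in% c("element", "graph", "pair")]
  gf <- matrix(NA_real_, nrow = n, ncol = length(feat_cols),
               dimnames = list(NULL, feat_cols))
  for (i in seq_len(n)) {
    v <- graph_features_one(h$sdf[[i]], pair_names)
    gf[i, ] <- v[feat_cols]
  }
  out[, feat_cols] <- gf

  sm_rows <- which(manifest$class %in% c("smarts_env", "fg_smarts"))
  for (j in sm_rows) {
    out[, j] <- suppressWarnings(smarts_counts(h$obmols, manifest$p1[j]))
  }

  bad <- !is.finite(out)
  if (any(bad)) {
    out[bad] <- rep(manifest$center, each = n)[bad]
    inform(sprintf("descriptor imputation applied to %d value(s)", sum(bad)))
  }
  out
}

#' @rdname descriptors
#' @export
descriptor_vector <- function(smiles, manifest = default_descriptor_manifest(),
                              scaled = TRUE) {
  stopifnot(length(smiles) == 1)
  drop(descriptor_matrix(smiles, manifest, scaled))
}

#' Functional-group counters
#'
#' Counts the 84 functional groups of the shipped SMARTS pattern table for
#' each molecule (raw non-negative integer counts, no scaling). This is the
#' counter block used by the linear group-contribution baseline and the tail
#' sub-block of the full descriptor vector.
#'
#' @param smiles Character vector of SMILES.
#' @param manifest Descriptor manifest supplying the pattern table.
#' @return An integer matrix, one row per molecule, 84 named columns.
#' @export
#' @examples
#' functional_group_counts(c("CCO", "CC(=O)OCC", "OCC(O)CO"))[, "fg_hydroxyl"]
functional_group_counts <- function(smiles,
                                    manifest = default_descriptor_manifest()) {
  m <- descriptor_matrix(smiles, manifest, scaled = FALSE)
  fg <- m[, manifest$class == "fg_smarts", drop = FALSE]
  storage.mode(fg) <- "integer"
  fg
}

# Build a manifest tibble; when reference SMILES are given, freeze centers
# and scales from their raw descriptor distribution (sd; constant -> 1).
build_descriptor_manifest <- function(reference_smiles = NULL,
                                      version = "descriptor_manifest_v1.csv") {
  def <- descriptor_definitions()
  def$center <- 0
  def$scale <- 1
  attr(def, "version") <- version
  class(def) <- c("descriptor_manifest", class(def))
  if (!is.null(reference_smiles)) {
    raw <- descriptor_matrix(reference_smiles, manifest = def, scaled = FALSE)
    ctr <- colMeans(raw)
    sc <- apply(raw, 2, sd)
    sc[!is.finite(sc) | sc < 1e-9] <- 1
    def$center <- as.numeric(ctr)
    def$scale <- as.numeric(sc)
  }
  def
}
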