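# Internal molecular-graph layer.
#
# Molecules are held as a pair of tables: atoms (stable integer id, element
# symbol) and bonds (two atom ids, integer order). Hydrogens are implicit
# unless added explicitly; the implicit count per heavy atom follows the
# usual organic-subset valence conventions, so graph edits (the rewriting
# engine, bond formation during assembly) automatically rebalance hydrogens
# and therefore masses. SMILES parsing and canonical SMILES generation go
# through OpenBabel (ChemmineOB); stereochemistry is stripped on input
# because downstream matching works on 2D achiral structures.

.MONO_MASS <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, F = 18.99840322, Cl = 34.96885268,
  Br = 78.9183371, I = 126.904473
)
.DEFAULT_VALENCE <- c(H = 1, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)
.MAX_VALENCE <- c(H = 1, C = 4, N = 3, O = 2, P = 5, S = 6,
                  F = 1, Cl = 1, Br = 1, I = 1)
.MASS_H2O <- 18.01056468403
.MASS_PROTON <- 1.007276466879

#' @keywords internal
mg_new <- function(elems, bonds = NULL) {
  elems <- as.character(elems)
  bad <- setdiff(unique(elems), names(.MONO_MASS))
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds) <- c("a1", "a2", "order")
    bonds[] <- lapply(bonds, as.integer)
  }
  structure(list(
    atoms = data.frame(id = seq_along(elems), elem = elems,
                       stringsAsFactors = FALSE),
    bonds = bonds
  ), class = "molgraph")
}

mg_n_atoms <- function(mg) nrow(mg$atoms)

# sum of bond orders per atom id (explicit degree weighted by order)
mg_bond_order_sum <- function(mg) {
  s <- setNames(numeric(nrow(mg$atoms)), mg$atoms$id)
  if (nrow(mg$bonds)) {
    for (k in seq_len(nrow(mg$bonds))) {
      b <- mg$bonds[k, ]
      s[as.character(b$a1)] <- s[as.character(b$a1)] + b$order
      s[as.character(b$a2)] <- s[as.character(b$a2)] + b$order
    }
  }
  s
}

mg_implicit_h <- function(mg) {
  s <- mg_bond_order_sum(mg)
  v <- .DEFAULT_VALENCE[mg$atoms$elem]
  pmax(0, v - s)
}

# TRUE if every atom's explicit bond-order sum is within its maximum valence
mg_valence_ok <- function(mg) {
  s <- mg_bond_order_sum(mg)
  all(s <= .MAX_VALENCE[mg$atoms$elem])
}

mg_formula <- function(mg) {
  counts <- table(mg$atoms$elem)
  f <- setNames(as.integer(counts), names(counts))
  nh <- sum(mg_implicit_h(mg))
  f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0L) + as.integer(nh)
  f <- f[f > 0]
  f[order(match(names(f), c("C", "H", names(.MONO_MASS))))]
}

mg_mass <- function(mg) {
  f <- mg_formula(mg)
  sum(.MONO_MASS[names(f)] * f)
}

formula_mass <- function(formula) {
  # "H2O" / "C6H12O6" style formula string
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  tot <- 0
  for (p in parts) {
    el <- sub("[0-9]+$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.MONO_MASS)) stop("unknown element in formula: ", el)
    tot <- tot + .MONO_MASS[[el]] * n
  }
  tot
}

mg_to_igraph <- function(mg) {
  g <- igraph::make_empty_graph(n = nrow(mg$atoms), directed = FALSE)
  igraph::V(g)$atom_id <- mg$atoms$id
  igraph::V(g)$elem <- mg$atoms$elem
  if (nrow(mg$bonds)) {
    idx <- match(c(rbind(mg$bonds$a1, mg$bonds$a2)), mg$atoms$id)
    g <- igraph::add_edges(g, idx)
    igraph::E(g)$order <- mg$bonds$order
  }
  g
}

mg_is_connected <- function(mg) {
  if (nrow(mg$atoms) <= 1) return(TRUE)
  igraph::is_connected(mg_to_igraph(mg))
}

# --- editing primitives (used by assembly and the rewriting engine) -------

mg_add_atom <- function(mg, elem) {
  if (!elem %in% names(.MONO_MASS)) stop("unsupported element: ", elem)
  new_id <- if (nrow(mg$atoms)) max(mg$atoms$id) + 1L else 1L
  mg$atoms <- rbind(mg$atoms, data.frame(id = new_id, elem = elem,
                                         stringsAsFactors = FALSE))
  attr(mg, "last_atom_id") <- new_id
  mg
}

mg_remove_atom <- function(mg, id) {
  if (!id %in% mg$atoms$id) stop("no atom with id ", id)
  mg$atoms <- mg$atoms[mg$atoms$id != id, , drop = FALSE]
  mg$bonds <- mg$bonds[mg$bonds$a1 != id & mg$bonds$a2 != id, , drop = FALSE]
  mg
}

# set the bond order between two atoms; order 0 removes the bond
mg_set_bond <- function(mg, i, j, order) {
  if (!all(c(i, j) %in% mg$atoms$id)) stop("bond references unknown atom id")
  if (i == j) stop("self-bond not allowed")
  hit <- (mg$bonds$a1 == i & mg$bonds$a2 == j) |
         (mg$bonds$a1 == j & mg$bonds$a2 == i)
  mg$bonds <- mg$bonds[!hit, , drop = FALSE]
  if (order > 0)
    mg$bonds <- rbind(mg$bonds,
                      data.frame(a1 = as.integer(i), a2 = as.integer(j),
                                 order = as.integer(order)))
  mg
}

# disjoint union; returns list(mg, offset) where ids of m2 got offset added
mg_combine <- function(m1, m2) {
  off <- if (nrow(m1$atoms)) max(m1$atoms$id) else 0L
  a2 <- m2$atoms; a2$id <- a2$id + off
  b2 <- m2$bonds
  if (nrow(b2)) { b2$a1 <- b2$a1 + off; b2$a2 <- b2$a2 + off }
  m1$atoms <- rbind(m1$atoms, a2)
  m1$bonds <- rbind(m1$bonds, b2)
  list(mg = m1, offset = off)
}

# --- SMILES / molfile I/O -------------------------------------------------

strip_stereo_smiles <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}

#' @keywords internal
mg_to_molfile <- function(mg, title = "glycomine") {
  na <- nrow(mg$atoms); nb <- nrow(mg$bonds)
  idx <- setNames(seq_len(na), mg$atoms$id)
  hdr <- c(title, "  glycomine", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    mg$atoms$elem)
  bd <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                        idx[as.character(mg$bonds$a1)],
                        idx[as.character(mg$bonds$a2)],
                        mg$bonds$order) else character()
  paste(c(hdr, at, bd, "M  END", "$$$$", ""), collapse = "\n")
}

parse_molfile <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  cl <- grep("V2000", lines)[1]
  if (is.na(cl)) stop("SMILES/molfile conversion failed (no V2000 block)")
  na <- as.integer(substr(lines[cl], 1, 3))
  nb <- as.integer(substr(lines[cl], 4, 6))
  if (is.na(na) || na < 1) stop("empty molecule")
  at <- lines[(cl + 1):(cl + na)]
  elems <- trimws(substr(at, 32, 34))
  bonds <- NULL
  if (nb > 0) {
    bl <- lines[(cl + na + 1):(cl + na + nb)]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
    if (any(bonds$order > 3))
      stop("aromatic/query bond orders are not supported")
  }
  mg_new(elems, bonds)
}

#' Parse a SMILES string into the internal molecular graph
#'
#' Stereochemistry marks are stripped before parsing; atom order follows the
#' order of first appearance in the SMILES string (the convention used by
#' catalog atom indices).
#'
#' @param smiles a single SMILES string.
#' @return an internal `molgraph` object.
#' @keywords internal
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  s <- strip_stereo_smiles(smiles)
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(s, "\n"))
  if (!nzchar(sdf) || !grepl("V2000", sdf))
    stop("unparseable SMILES: ", smiles)
  parse_molfile(sdf)
}

#' Canonical stereochemistry-free SMILES
#'
#' Returns the OpenBabel canonical SMILES of a structure with all
#' stereochemistry removed, so that two spellings of the same 2D molecular
#' graph map to one string.
#'
#' @param x a SMILES string or an internal molgraph.
#' @return a single canonical SMILES string.
#' @export
#' @examples
#' \donttest{
#' canonical_smiles("OCC1OC(O)C(O)C(O)C1O")
#' }
canonical_smiles <- function(x) {
  mf <- if (inherits(x, "molgraph")) mg_to_molfile(x)
        else mg_to_molfile(parse_smiles(x))
  out <- ChemmineOB::convertFormat("SDF", "CAN", mf)
  out <- strsplit(out, "[ \t\n]")[[1]][1]
  if (is.na(out) || !nzchar(out))
    stop("canonicalization failed")
  strip_stereo_smiles(out)
}

#' Monoisotopic mass of a structure
#'
#' Computed from the elemental composition (implicit hydrogens included)
#' using monoisotopic atomic masses.
#'
#' @param x a SMILES string or an internal molgraph.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(x) {
  mg <- if (inherits(x, "molgraph")) x else parse_smiles(x)
  unname(mg_mass(mg))
}
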