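# Postassembly-modification engine.
#
# A modification rule is a substrate motif (SMILES fragment) plus an ordered
# command program over {add, remove, connect, disconnect}. Command atom
# indices are stable ids: 1..n for the motif atoms in SMILES appearance
# order, with added atoms continuing the numbering ("add 3 N" creates atom
# 3). "connect i j k" sets the bond order between i and j to k (creating
# the bond if absent); "disconnect i j" removes an existing bond. Replaying
# a program on a structure at a matched site must leave a valence-legal,
# connected product whose mass change equals the rule's stored delta;
# sites where that fails are skipped.

parse_commands <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(list())
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  lapply(parts, function(p) {
    tok <- strsplit(p, "[[:space:]]+")[[1]]
    op <- tok[1]
    switch(op,
      add = {
        if (length(tok) != 3) stop("malformed add command: ", p)
        list(op = "add", index = as.integer(tok[2]), elem = tok[3])
      },
      remove = {
        if (length(tok) != 2) stop("malformed remove command: ", p)
        list(op = "remove", index = as.integer(tok[2]))
      },
      connect = {
        if (length(tok) != 4) stop("malformed connect command: ", p)
        list(op = "connect", i = as.integer(tok[2]), j = as.integer(tok[3]),
             order = as.integer(tok[4]))
      },
      disconnect = {
        if (length(tok) != 3) stop("malformed disconnect command: ", p)
        list(op = "disconnect", i = as.integer(tok[2]), j = as.integer(tok[3]))
      },
      stop("unknown command: ", op)
    )
  })
}

# Replay a command program against a structure. `mapping` maps command
# indices (motif numbering) to atom ids of `mg`; added atoms extend it.
apply_commands <- function(mg, program, mapping) {
  mapping <- as.list(mapping)
  resolve <- function(idx) {
    if (idx > length(mapping) || is.null(mapping[[idx]]) ||
        is.na(mapping[[idx]]))
      stop("command references unmapped or removed atom index ", idx)
    mapping[[idx]]
  }
  for (cmd in program) {
    if (cmd$op == "add") {
      mg <- mg_add_atom(mg, cmd$elem)
      mapping[[cmd$index]] <- attr(mg, "last_atom_id")
    } else if (cmd$op == "remove") {
      id <- resolve(cmd$index)
      mg <- mg_remove_atom(mg, id)
      mapping[[cmd$index]] <- NA_integer_
    } else if (cmd$op == "connect") {
      mg <- mg_set_bond(mg, resolve(cmd$i), resolve(cmd$j), cmd$order)
    } else { # disconnect
      i <- resolve(cmd$i); j <- resolve(cmd$j)
      hit <- (mg$bonds$a1 == i & mg$bonds$a2 == j) |
             (mg$bonds$a1 == j & mg$bonds$a2 == i)
      if (!any(hit))
        stop("disconnect: no bond between indices ", cmd$i, " and ", cmd$j)
      mg <- mg_set_bond(mg, i, j, 0L)
    }
  }
  mg
}

#' Find all embeddings of a substrate motif in a structure
#'
#' Subgraph matching with element-constrained domains (igraph LAD solver,
#' non-induced) followed by a bond-order filter and a hydrogen-availability
#' filter: a motif heteroatom drawn with at least one implicit hydrogen
#' (e.g. the hydroxyl oxygen in motif \code{CO}) only matches structure
#' atoms that still carry one, so ring/ether oxygens are not mistaken for
#' hydroxyls. Symmetric duplicates are collapsed to one mapping per site
#' signature (the sorted set of matched atoms).
#'
#' @param structure SMILES string or internal molgraph.
#' @param motif_smiles motif SMILES fragment.
#' @return list of integer vectors; element k of a vector is the structure
#'   atom id matched to motif atom k.
#' @export
match_motif <- function(structure, motif_smiles) {
  mg <- if (inherits(structure, "molgraph")) structure
        else parse_smiles(structure)
  motif <- tryCatch(parse_smiles(motif_smiles),
                    error = function(e) stop("unparseable motif: ",
                                             motif_smiles))
  gt <- mg_to_igraph(mg)
  gp <- mg_to_igraph(motif)
  ht <- mg_implicit_h(mg)
  hp <- mg_implicit_h(motif)
  dt <- igraph::degree(gt)
  dp <- igraph::degree(gp)
  # element (+ degree, + heteroatom-H availability) domains per motif atom
  domains <- lapply(seq_len(nrow(motif$atoms)), function(k) {
    ok <- mg$atoms$elem == motif$atoms$elem[k] & dt >= dp[k]
    if (motif$atoms$elem[k] != "C" && hp[k] >= 1) ok <- ok & ht >= 1
    which(ok)
  })
  if (any(lengths(domains) == 0)) return(list())
  maps <- igraph::subgraph_isomorphisms(gp, gt, method = "lad",
                                        induced = FALSE, domains = domains)
  if (!length(maps)) return(list())
  # bond-order filter
  ord_lookup <- new.env(hash = TRUE)
  if (nrow(mg$bonds))
    for (k in seq_len(nrow(mg$bonds)))
      assign(paste(sort(c(mg$bonds$a1[k], mg$bonds$a2[k])), collapse = "-"),
             mg$bonds$order[k], envir = ord_lookup)
  keep <- vapply(maps, function(m) {
    ids <- mg$atoms$id[as.vector(m)]
    all(vapply(seq_len(nrow(motif$bonds)), function(b) {
      key <- paste(sort(c(ids[motif$bonds$a1[b]], ids[motif$bonds$a2[b]])),
                   collapse = "-")
      o <- mget(key, envir = ord_lookup, ifnotfound = list(NA))[[1]]
      !is.na(o) && o == motif$bonds$order[b]
    }, TRUE))
  }, TRUE)
  maps <- maps[keep]
  if (!length(maps)) return(list())
  out <- lapply(maps, function(m) mg$atoms$id[as.vector(m)])
  # collapse automorphic images: one representative per sorted atom set
  sig <- vapply(out, function(v) paste(sort(v), collapse = ","), "")
  ordr <- order(vapply(out, function(v) paste(v, collapse = ","), ""))
  out <- out[ordr][!duplicated(sig[ordr])]
  out
}

#' Apply one modification rule at a matched site
#'
#' @param structure SMILES string or internal molgraph.
#' @param rule a rule record as returned by the knowledge base.
#' @param site an atom-id mapping from [match_motif()].
#' @param check verify valence legality, connectivity and the mass delta
#'   (default TRUE); an invalid product raises an error.
#' @return modified internal molgraph.
#' @export
apply_rule <- function(structure, rule, site, check = TRUE) {
  mg <- if (inherits(structure, "molgraph")) structure
        else parse_smiles(structure)
  before <- mg_mass(mg)
  out <- apply_commands(mg, rule$program, site)
  if (check) {
    if (!mg_valence_ok(out))
      stop("rule ", rule$id, ": product violates valence at this site")
    if (!mg_is_connected(out))
      stop("rule ", rule$id, ": product is disconnected at this site")
    if (abs(mg_mass(out) - before - rule$mass_delta) > 1e-4)
      stop("rule ", rule$id, ": observed mass change ",
           format(mg_mass(out) - before, digits = 10),
           " != stored delta ", format(rule$mass_delta, digits = 10))
  }
  out
}

#' Validate a modification rule by replaying it on its own motif
#'
#' Replays the command program against the bare motif and reports whether
#' the product is chemically valid (valence-legal, connected) and whether
#' the observed mass change matches the stored \code{mass_delta} within
#' \code{tol}.
#'
#' @param rule a rule record (id, motif_smiles, program, mass_delta).
#' @param tol mass agreement tolerance in Da (default 1e-4).
#' @return list with elements `valid`, `mass_ok`, `observed_delta`,
#'   `product_smiles`, `messages`.
#' @export
validate_modification_rule <- function(rule, tol = 1e-4) {
  msgs <- character()
  motif <- tryCatch(parse_smiles(rule$motif_smiles), error = function(e) {
    msgs <<- c(msgs, paste("motif does not parse:", conditionMessage(e)))
    NULL
  })
  if (is.null(motif))
    return(list(valid = FALSE, mass_ok = FALSE, observed_delta = NA_real_,
                product_smiles = NA_character_, messages = msgs))
  prod <- tryCatch(apply_commands(motif, rule$program, motif$atoms$id),
                   error = function(e) {
    msgs <<- c(msgs, paste("command replay failed:", conditionMessage(e)))
    NULL
  })
  if (is.null(prod))
    return(list(valid = FALSE, mass_ok = FALSE, observed_delta = NA_real_,
                product_smiles = NA_character_, messages = msgs))
  ok <- TRUE
  if (!mg_valence_ok(prod)) { ok <- FALSE; msgs <- c(msgs, "valence violation") }
  if (nrow(prod$atoms) == 0) { ok <- FALSE; msgs <- c(msgs, "empty product") }
  if (ok && !mg_is_connected(prod)) {
    ok <- FALSE; msgs <- c(msgs, "disconnected product")
  }
  delta <- if (nrow(prod$atoms)) mg_mass(prod) - mg_mass(motif) else NA_real_
  mass_ok <- isTRUE(abs(delta - rule$mass_delta) <= tol)
  if (!mass_ok)
    msgs <- c(msgs, sprintf("mass delta mismatch: observed %.5f, stored %.5f",
                            delta, rule$mass_delta))
  list(valid = ok && mass_ok, mass_ok = mass_ok, observed_delta = delta,
       product_smiles = if (ok) canonical_smiles(prod) else NA_character_,
       messages = msgs)
}

#' Rules activated by a BGC presence vector
#'
#' A rule is active when all of its enzyme gene classes are present
#' (multi-enzyme rules require every listed class).
#'
#' @param kb a `glyco_kb`.
#' @param presence a binary presence vector named by gene-class id, or a
#'   character vector of present class ids.
#' @return character vector of active rule ids.
#' @export
active_rules <- function(kb, presence) {
  present <- if (is.character(presence)) presence
             else names(presence)[presence > 0]
  kb$modifications$id[vapply(kb$modifications$enzyme_gene_classes,
                             function(cl) all(cl %in% present), TRUE)]
}

#' Enumerate mature candidates from a backbone
#'
#' Emits the unmodified backbone plus all products of applying the active
#' rules at their matching sites, composing up to `depth` applications per
#' molecule, deduplicated by canonical SMILES. Rule application order is
#' normalized (sorted rule id) and sites failing chemistry checks are
#' skipped, so the output is independent of rule iteration order.
#'
#' @param backbone SMILES string or molgraph of an assembled backbone.
#' @param kb a `glyco_kb`.
#' @param rules character vector of active rule ids (see [active_rules()]).
#' @param depth maximum number of applied rules per molecule (default 3).
#' @param max_candidates cap on emitted candidates (default 1000); hitting
#'   the cap truncates with a warning.
#' @return data.frame with columns `smiles`, `monoisotopic_mass`,
#'   `applied_rules` (semicolon-joined "rule@site" provenance), `n_mods`.
#' @export
enumerate_mature <- function(backbone, kb, rules, depth = 3,
                             max_candidates = 1000) {
  mg0 <- if (inherits(backbone, "molgraph")) backbone
         else parse_smiles(backbone)
  rules <- sort(rules)
  base_smi <- canonical_smiles(mg0)
  seen <- new.env(hash = TRUE)
  assign(base_smi, TRUE, envir = seen)
  res <- data.frame(smiles = base_smi, monoisotopic_mass = mg_mass(mg0),
                    applied_rules = "", n_mods = 0L,
                    stringsAsFactors = FALSE)
  frontier <- list(list(mg = mg0, prov = character()))
  truncated <- FALSE
  d <- 0L
  while (length(frontier) && d < depth && !truncated) {
    d <- d + 1L
    nxt <- list()
    for (node in frontier) {
      for (rid in rules) {
        rule <- kb_rule(kb, rid)
        sites <- match_motif(node$mg, rule$motif_smiles)
        for (site in sites) {
          prod <- tryCatch(apply_rule(node$mg, rule, site, check = TRUE),
                           error = function(e) NULL)
          if (is.null(prod)) next   # chemistry check failed: skip site
          smi <- canonical_smiles(prod)
          if (exists(smi, envir = seen, inherits = FALSE)) next
          assign(smi, TRUE, envir = seen)
          prov <- c(node$prov,
                    paste0(rid, "@", paste(sort(site), collapse = ".")))
          res <- rbind(res, data.frame(
            smiles = smi, monoisotopic_mass = mg_mass(prod),
            applied_rules = paste(prov, collapse = ";"),
            n_mods = length(prov), stringsAsFactors = FALSE))
          nxt[[length(nxt) + 1L]] <- list(mg = prod, prov = prov)
          if (nrow(res) >= max_candidates) { truncated <- TRUE; break }
        }
        if (truncated) break
      }
      if (truncated) break
    }
    frontier <- nxt
  }
  if (truncated)
    warning("mature-candidate cap reached (", max_candidates,
            "); output truncated")
  rownames(res) <- NULL
  res
}
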