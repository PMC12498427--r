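# Combinatorial backbone assembly.
#
# A ranked monomer multiset is assembled into linear chains: every distinct
# ordering of the multiset is considered, and at each junction every
# compatible (bond rule, donor reactive group, acceptor reactive group,
# orientation) choice is enumerated. Bond formation is a condensation: the
# donor's leaving oxygen (the activated-anomeric placeholder for
# glycosylation, the donor hydroxyl for dehydration, the carboxyl hydroxyl
# for amidation) is excised and the donor carbon is bonded to the acceptor
# heteroatom, so each junction loses one H2O and terminal monomers consume
# exactly one reactive group while internal monomers consume two. Results
# are deduplicated by canonical SMILES. Branching is not enumerated.

# atom id of the carbon carrying a donor group, and the atom to excise
donor_attachment <- function(mg, group_type, atom_id) {
  nb <- c(mg$bonds$a2[mg$bonds$a1 == atom_id],
          mg$bonds$a1[mg$bonds$a2 == atom_id])
  if (group_type %in% c("activated-anomeric", "hydroxyl")) {
    # the O leaves; its (unique) carbon neighbour forms the new bond
    if (length(nb) != 1) return(NULL)
    list(bond_atom = nb[1], excise = atom_id)
  } else if (group_type == "carboxyl") {
    # atom_id is the carboxyl carbon; its single-bonded O leaves
    singles <- mg$bonds[(mg$bonds$a1 == atom_id | mg$bonds$a2 == atom_id) &
                          mg$bonds$order == 1, , drop = FALSE]
    ocand <- setdiff(c(singles$a1, singles$a2), atom_id)
    ocand <- ocand[mg$atoms$elem[match(ocand, mg$atoms$id)] == "O"]
    # the hydroxyl O: degree-1 oxygen attached to this carbon
    deg <- vapply(ocand, function(o)
      sum(mg$bonds$a1 == o | mg$bonds$a2 == o), 0L)
    ocand <- ocand[deg == 1]
    if (!length(ocand)) return(NULL)
    list(bond_atom = atom_id, excise = min(ocand))
  } else NULL
}

# distinct permutations of a multiset given as a named count vector
multiset_permutations <- function(counts) {
  out <- list()
  ids <- names(counts)
  recurse <- function(counts, acc) {
    if (all(counts == 0)) { out[[length(out) + 1L]] <<- acc; return() }
    for (id in ids[counts > 0]) {
      counts2 <- counts; counts2[id] <- counts2[id] - 1L
      recurse(counts2, c(acc, id))
    }
  }
  recurse(counts, character())
  out
}

#' Assemble candidate linear backbones from a monomer multiset
#'
#' Enumerates all orderings of the multiset and all compatible bond-rule /
#' reactive-group choices per junction, discards assemblies that violate
#' reactive-group accounting, verifies mass conservation (sum of monomer
#' masses minus one leaving group per bond) for every emitted candidate,
#' and deduplicates by canonical SMILES. Monomer multisets with no valid
#' assembly yield an empty result.
#'
#' @param monomer_ids character vector of monomer ids, repeats allowed
#'   (multiset semantics: input order is irrelevant).
#' @param kb a `glyco_kb`.
#' @param max_backbones cap on emitted candidates (default 5000); reaching
#'   it truncates with a warning.
#' @param cyclize also attempt a terminal-to-terminal closing bond when a
#'   compatible pair of unused terminal groups remains (default FALSE).
#' @return data.frame with columns `backbone_id`, `smiles`,
#'   `monoisotopic_mass`, `monomer_order`, `bonds` (junction provenance).
#' @export
assemble_backbones <- function(monomer_ids, kb, max_backbones = 5000,
                               cyclize = FALSE) {
  if (!length(monomer_ids)) stop("empty monomer set")
  counts <- table(monomer_ids)
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  mono_rows <- lapply(setNames(nm = names(counts)), function(id)
    kb_monomer(kb, id))
  rules <- kb$bond_rules

  emit <- new.env(hash = TRUE)
  results <- list()
  truncated <- FALSE

  build <- function(order_ids, plan) {
    # materialize: union graph, then apply each junction condensation
    union <- mg_new(character())
    offsets <- integer(length(order_ids))
    grouptab <- list()
    for (i in seq_along(order_ids)) {
      row <- mono_rows[[order_ids[i]]]
      cmb <- mg_combine(union, row$graph[[1]])
      union <- cmb$mg
      offsets[i] <- cmb$offset
      grouptab[[i]] <- row$groups[[1]]
    }
    total_mass <- sum(vapply(order_ids, function(id)
      mono_rows[[id]]$monoisotopic_mass, 0))
    leaving <- 0
    for (jn in plan) {
      rule <- rules[jn$rule, ]
      dpos <- jn$donor_pos; apos <- jn$acceptor_pos
      datom <- grouptab[[dpos]]$atom_index[jn$donor_g] + offsets[dpos]
      aatom <- grouptab[[apos]]$atom_index[jn$acceptor_g] + offsets[apos]
      att <- donor_attachment(union, rule$donor_group_type, datom)
      if (is.null(att)) return(invisible(NULL))
      union <- mg_remove_atom(union, att$excise)
      union <- mg_set_bond(union, att$bond_atom, aatom, 1L)
      leaving <- leaving + rule$leaving_mass
    }
    if (!mg_valence_ok(union) || !mg_is_connected(union))
      return(invisible(NULL))
    mass <- mg_mass(union)
    if (abs(mass - (total_mass - leaving)) > 1e-4)
      stop("mass bookkeeping violated during assembly")   # nocov
    smi <- canonical_smiles(union)
    if (exists(smi, envir = emit, inherits = FALSE)) return(invisible(NULL))
    assign(smi, TRUE, envir = emit)
    results[[length(results) + 1L]] <<- data.frame(
      smiles = smi, monoisotopic_mass = mass,
      monomer_order = paste(order_ids, collapse = ","),
      bonds = paste(vapply(plan, function(jn)
        sprintf("%s:%d>%d", rules$id[jn$rule], jn$donor_pos,
                jn$acceptor_pos), ""), collapse = ";"),
      stringsAsFactors = FALSE)
    invisible(NULL)
  }

  for (order_ids in multiset_permutations(counts)) {
    if (truncated) break
    n <- length(order_ids)
    grouptabs <- lapply(order_ids, function(id)
      mono_rows[[id]]$groups[[1]])
    # recursively choose junction assignments with per-instance group use
    assign_junction <- function(j, used, plan) {
      if (truncated) return()
      if (j > n - 1) {
        build(order_ids, plan)
        if (length(results) >= max_backbones) truncated <<- TRUE
        if (cyclize && n >= 2) {
          # optional ring closure between the two chain termini
          for (r in seq_len(nrow(rules))) {
            for (orient in list(c(1L, n), c(n, 1L))) {
              dpos <- orient[1]; apos <- orient[2]
              dg <- which(grouptabs[[dpos]]$type ==
                            rules$donor_group_type[r])
              ag <- which(grouptabs[[apos]]$type ==
                            rules$acceptor_group_type[r])
              for (di in dg) for (ai in ag) {
                if (used[[dpos]][di] || used[[apos]][ai]) next
                build(order_ids, c(plan, list(list(
                  rule = r, donor_pos = dpos, donor_g = di,
                  acceptor_pos = apos, acceptor_g = ai))))
                if (length(results) >= max_backbones) truncated <<- TRUE
              }
            }
          }
        }
        return()
      }
      for (r in seq_len(nrow(rules))) {
        for (orient in list(c(j, j + 1L), c(j + 1L, j))) {
          dpos <- orient[1]; apos <- orient[2]
          dg <- which(grouptabs[[dpos]]$type == rules$donor_group_type[r])
          ag <- which(grouptabs[[apos]]$type == rules$acceptor_group_type[r])
          for (di in dg) for (ai in ag) {
            if (used[[dpos]][di] || used[[apos]][ai]) next
            used2 <- used
            used2[[dpos]][di] <- TRUE
            used2[[apos]][ai] <- TRUE
            assign_junction(j + 1L, used2, c(plan, list(list(
              rule = r, donor_pos = dpos, donor_g = di,
              acceptor_pos = apos, acceptor_g = ai))))
            if (truncated) return()
          }
        }
      }
    }
    used0 <- lapply(grouptabs, function(g) rep(FALSE, nrow(g)))
    assign_junction(1L, used0, list())
  }
  if (truncated)
    warning("backbone cap reached (", max_backbones, "); output truncated")
  if (!length(results))
    return(data.frame(backbone_id = character(), smiles = character(),
                      monoisotopic_mass = numeric(),
                      monomer_order = character(), bonds = character()))
  res <- do.call(rbind, results)
  res <- res[order(res$smiles), , drop = FALSE]
  res <- cbind(backbone_id = sprintf("bb%04d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}
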