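# Knowledge-base loading and validation.
#
# Four TSV catalogs drive the pipeline: gene classes (the G enzyme classes
# the HMM annotation reports), monomers (K primary + secondary sugar /
# aminocyclitol building blocks with 2D achiral SMILES and reactive-group
# annotations), bond-formation rules, and postassembly-modification rules
# (motif SMILES + graph-edit command program). Catalogs are plain TSV with
# a versioned comment header so they stay diffable and hand-curatable.

.REACTIVE_GROUP_TYPES <- c("hydroxyl", "amine", "activated-anomeric",
                           "carboxyl", "ketone")
.GROUP_ELEMENT <- c("hydroxyl" = "O", "amine" = "N",
                    "activated-anomeric" = "O", "carboxyl" = "C",
                    "ketone" = "C")

kb_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "glycomine_kb_error")))
}

read_catalog <- function(path) {
  if (!file.exists(path))
    kb_error("glycomine_missing_file", paste("catalog file not found:", path))
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = character(),
                    colClasses = "character")
}

parse_reactive_groups <- function(txt, monomer_id) {
  if (!nzchar(txt)) return(data.frame(type = character(), atom_index = integer()))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  df <- data.frame(
    type = vapply(kv, `[`, "", 1),
    atom_index = as.integer(vapply(kv, `[`, "", 2))
  )
  bad <- setdiff(df$type, .REACTIVE_GROUP_TYPES)
  if (length(bad))
    kb_error("glycomine_unknown_group_type",
             paste0("monomer ", monomer_id, ": unknown reactive-group type ",
                    paste(bad, collapse = ", ")))
  df
}

split_ids <- function(txt, sep = ",") {
  if (is.na(txt) || !nzchar(txt)) return(character())
  trimws(strsplit(txt, sep, fixed = TRUE)[[1]])
}

#' Default knowledge-base catalog paths
#'
#' Paths of the packaged catalogs (gene classes, monomers, bond rules,
#' postassembly modifications).
#'
#' @return named list of file paths.
#' @export
kb_default_paths <- function() {
  d <- system.file("extdata", "kb", package = "glycomine")
  list(gene_classes = file.path(d, "gene_classes.tsv"),
       monomers = file.path(d, "monomers.tsv"),
       bond_rules = file.path(d, "bond_rules.tsv"),
       modifications = file.path(d, "modifications.tsv"))
}

#' Load and validate the knowledge base
#'
#' Reads the four catalogs, resolves cross-references, validates every
#' invariant (SMILES parse and are stereochemistry-free; reactive-group
#' atom indices address atoms of the right element; catalog cardinalities
#' match the configured G gene classes and K primary monomers; all three
#' bond-rule families present; every modification rule replays on its own
#' motif with a mass change matching its stored delta) and returns a
#' `glyco_kb` object with records ordered deterministically by id.
#'
#' @param paths named list as returned by [kb_default_paths()].
#' @param G expected number of gene classes (default 50).
#' @param K expected number of primary monomers (default 6).
#' @param n_modifications expected modification-catalog size (default 49);
#'   `NA` skips the cardinality check (used for reduced test catalogs).
#' @param n_secondary expected number of non-primary monomers (default 20);
#'   `NA` skips the check.
#' @param validate_rules replay every modification rule on load (default
#'   TRUE).
#' @return an object of class `glyco_kb`.
#' @export
load_knowledge_base <- function(paths = kb_default_paths(), G = 50, K = 6,
                                n_modifications = 49, n_secondary = 20,
                                validate_rules = TRUE) {
  gc <- read_catalog(paths$gene_classes)
  mono <- read_catalog(paths$monomers)
  bonds <- read_catalog(paths$bond_rules)
  mods <- read_catalog(paths$modifications)

  for (nm in list(list(gc, "gene class"), list(mono, "monomer"),
                  list(bonds, "bond rule"), list(mods, "modification"))) {
    if (anyDuplicated(nm[[1]]$id))
      kb_error("glycomine_duplicate_id",
               paste("duplicate", nm[[2]], "ids in catalog"))
  }
  gc <- gc[order(gc$id), , drop = FALSE]
  mono <- mono[order(mono$id), , drop = FALSE]
  bonds <- bonds[order(bonds$id), , drop = FALSE]
  mods <- mods[order(mods$id), , drop = FALSE]
  rownames(gc) <- rownames(mono) <- rownames(bonds) <- rownames(mods) <- NULL

  # cardinalities
  if (nrow(gc) != G)
    kb_error("glycomine_cardinality_mismatch",
             sprintf("gene-class catalog has %d records, configured G = %d",
                     nrow(gc), G))
  mono$is_primary <- mono$is_primary == "1"
  if (sum(mono$is_primary) != K)
    kb_error("glycomine_cardinality_mismatch",
             sprintf("%d primary monomers, configured K = %d",
                     sum(mono$is_primary), K))
  if (!is.na(n_secondary) && sum(!mono$is_primary) != n_secondary)
    kb_error("glycomine_cardinality_mismatch",
             sprintf("%d secondary monomers, expected %d",
                     sum(!mono$is_primary), n_secondary))
  if (!is.na(n_modifications) && nrow(mods) != n_modifications)
    kb_error("glycomine_cardinality_mismatch",
             sprintf("%d modification rules, expected %d",
                     nrow(mods), n_modifications))

  # monomers: SMILES, masses, reactive groups
  mono$smiles <- strip_stereo_smiles(mono$smiles)
  graphs <- vector("list", nrow(mono))
  groups <- vector("list", nrow(mono))
  for (i in seq_len(nrow(mono))) {
    mg <- tryCatch(parse_smiles(mono$smiles[i]), error = function(e)
      kb_error("glycomine_malformed_smiles",
               paste0("monomer ", mono$id[i], ": ", conditionMessage(e))))
    g <- parse_reactive_groups(mono$reactive_groups[i], mono$id[i])
    if (nrow(g)) {
      if (any(g$atom_index < 1 | g$atom_index > nrow(mg$atoms)))
        kb_error("glycomine_bad_atom_index",
                 paste0("monomer ", mono$id[i],
                        ": reactive-group atom index out of range"))
      expected <- .GROUP_ELEMENT[g$type]
      got <- mg$atoms$elem[g$atom_index]
      if (any(expected != got))
        kb_error("glycomine_bad_atom_index",
                 paste0("monomer ", mono$id[i],
                        ": reactive-group atom has wrong element"))
    }
    graphs[[i]] <- mg
    groups[[i]] <- g
  }
  mono$monoisotopic_mass <- vapply(graphs, mg_mass, 0)
  mono$required_gene_classes <- lapply(mono$required_gene_classes, split_ids)
  mono$groups <- groups
  mono$graph <- graphs
  if (any(!mono$is_primary &
          lengths(mono$required_gene_classes) == 0))
    kb_error("glycomine_dangling_reference",
             "secondary monomer without required gene classes")
  if (any(mono$is_primary & lengths(mono$required_gene_classes) > 0))
    kb_error("glycomine_dangling_reference",
             "primary monomer must not require gene classes")

  # gene classes: roles resolve
  gc$monomer_roles <- lapply(gc$monomer_roles, split_ids)
  gc$modification_roles <- lapply(gc$modification_roles, split_ids)
  dangling <- c(setdiff(unlist(gc$monomer_roles), mono$id),
                setdiff(unlist(gc$modification_roles), mods$id),
                setdiff(unlist(mono$required_gene_classes), gc$id))
  if (length(dangling))
    kb_error("glycomine_dangling_reference",
             paste("dangling catalog reference(s):",
                   paste(unique(dangling), collapse = ", ")))

  # bond rules
  fams <- sort(unique(bonds$reaction_name))
  if (!identical(fams, c("amidation", "dehydration", "glycosylation")))
    kb_error("glycomine_cardinality_mismatch",
             paste("bond-rule families must be exactly amidation,",
                   "dehydration, glycosylation; got",
                   paste(fams, collapse = ", ")))
  if (!all(bonds$donor_group_type %in% .REACTIVE_GROUP_TYPES) ||
      !all(bonds$acceptor_group_type %in% .REACTIVE_GROUP_TYPES))
    kb_error("glycomine_unknown_group_type",
             "bond rule uses unknown reactive-group type")
  bonds$leaving_mass <- vapply(bonds$leaving_composition, formula_mass, 0)

  # modification rules
  mods$enzyme_gene_classes <- lapply(mods$enzyme_gene_classes, split_ids,
                                     sep = "+")
  dang <- setdiff(unlist(mods$enzyme_gene_classes), gc$id)
  if (length(dang))
    kb_error("glycomine_dangling_reference",
             paste("modification rule references unknown gene class:",
                   paste(unique(dang), collapse = ", ")))
  mods$motif_smiles <- strip_stereo_smiles(mods$motif_smiles)
  mods$mass_delta <- as.numeric(mods$mass_delta)
  mods$program <- lapply(mods$commands, parse_commands)

  kb <- structure(list(
    gene_classes = gc, monomers = mono, bond_rules = bonds,
    modifications = mods,
    config = list(G = G, K = K)
  ), class = "glyco_kb")

  if (validate_rules && nrow(mods)) {
    for (i in seq_len(nrow(mods))) {
      rep <- validate_modification_rule(kb_rule(kb, mods$id[i]))
      if (!rep$valid)
        kb_error("glycomine_invalid_rule",
                 paste0("modification rule ", mods$id[i],
                        " failed validation: ",
                        paste(rep$messages, collapse = "; ")))
    }
  }
  kb
}

#' @export
print.glyco_kb <- function(x, ...) {
  cat("glycomine knowledge base\n")
  cat(sprintf("  gene classes:       %d (G)\n", nrow(x$gene_classes)))
  cat(sprintf("  monomers:           %d (%d primary, %d secondary)\n",
              nrow(x$monomers), sum(x$monomers$is_primary),
              sum(!x$monomers$is_primary)))
  cat(sprintf("  bond rules:         %d in %d families\n",
              nrow(x$bond_rules), length(unique(x$bond_rules$reaction_name))))
  cat(sprintf("  modification rules: %d\n", nrow(x$modifications)))
  invisible(x)
}

# record accessors ---------------------------------------------------------

kb_monomer <- function(kb, id) {
  i <- match(id, kb$monomers$id)
  if (is.na(i)) kb_error("glycomine_dangling_reference",
                         paste("unknown monomer id:", id))
  kb$monomers[i, ]
}

#' Retrieve one modification-rule record
#'
#' @param kb a `glyco_kb`.
#' @param id rule id.
#' @return list with the rule fields (program parsed).
#' @export
kb_rule <- function(kb, id) {
  i <- match(id, kb$modifications$id)
  if (is.na(i)) kb_error("glycomine_dangling_reference",
                         paste("unknown modification rule id:", id))
  r <- kb$modifications[i, ]
  list(id = r$id, name = r$name,
       enzyme_gene_classes = r$enzyme_gene_classes[[1]],
       motif_smiles = r$motif_smiles, commands = r$commands,
       program = r$program[[1]], mass_delta = r$mass_delta)
}

# gene classes that carry at least one monomer (biosynthesis) role
kb_biosynthesis_classes <- function(kb) {
  kb$gene_classes$id[lengths(kb$gene_classes$monomer_roles) > 0]
}

# canonical serialization used by the idempotence/order-independence checks
kb_serialize <- function(kb) {
  flat <- function(df) {
    df$graph <- NULL
    df <- df[order(df$id), , drop = FALSE]
    paste(vapply(seq_len(nrow(df)), function(i)
      paste(vapply(df[i, ], function(col) {
        v <- col[[1]]
        if (is.data.frame(v)) v <- paste(v$type, v$atom_index, collapse = ";")
        paste(format(unlist(v), digits = 12), collapse = ",")
      }, ""), collapse = "\t"), ""), collapse = "\n")
  }
  paste(flat(kb$gene_classes), flat(kb$monomers), flat(kb$bond_rules),
        flat(kb$modifications), sep = "\n--\n")
}
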