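# Shared fixtures: the packaged knowledge base (loaded once per run) and a
# small toy knowledge base written to a temporary directory.

pkg_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- load_knowledge_base()
    kb
  }
})

pkg_model <- local({
  fit <- NULL
  function() {
    if (is.null(fit))
      fit <- fit_monomer_model(load_training_pairs(pkg_kb()))
    fit
  }
})

# toy catalogs: 8 gene classes, 2 primary + 3 secondary monomers with at
# most two reactive groups each, the standard bond-rule table, 2
# modification rules
write_toy_kb <- function(dir = tempfile("toykb")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    "id\tname\thmm_ref\tmonomer_roles\tmodification_roles",
    "ga01\tclass A synthase\tH1\ttA\t",
    "ga02\tclass B aminotransferase\tH2\ttB\t",
    "ga03\tclass C synthase\tH3\ttC\t",
    "ga04\tspare class 4\tH4\t\t",
    "ga05\tspare class 5\tH5\t\t",
    "ga06\tspare class 6\tH6\t\t",
    "ga07\ttoy O-methyltransferase\tH7\t\ttm1",
    "ga08\ttoy N-acetyltransferase\tH8\t\ttm2"
  ), file.path(dir, "gene_classes.tsv"))
  writeLines(c(
    "id\tname\tsmiles\treactive_groups\trequired_gene_classes\tis_primary",
    "tA\tdiol A\tOCCO\thydroxyl:1;hydroxyl:4\tga01\t0",
    "tB\tamino alcohol B\tNCCO\tamine:1;hydroxyl:4\tga02\t0",
    "tC\tactivated C\tCC(O)CO\tactivated-anomeric:3;hydroxyl:5\tga03\t0",
    "tP1\tprimary diol\tOCCCO\thydroxyl:1;hydroxyl:5\t\t1",
    "tP2\tprimary amino alcohol\tNCCCO\tamine:1;hydroxyl:5\t\t1"
  ), file.path(dir, "monomers.tsv"))
  file.copy(kb_default_paths()$bond_rules, file.path(dir, "bond_rules.tsv"))
  writeLines(c(
    "id\tname\tenzyme_gene_classes\tmotif_smiles\tcommands\tmass_delta",
    paste0("tm1\ttoy O-methylation\tga07\tCO\t",
           "add 3 C;connect 2 3 1\t14.01565006"),
    paste0("tm2\ttoy N-acetylation\tga08\tCN\t",
           "add 3 C;add 4 C;add 5 O;connect 2 3 1;connect 3 4 1;",
           "connect 3 5 2\t42.01056468")
  ), file.path(dir, "modifications.tsv"))
  list(gene_classes = file.path(dir, "gene_classes.tsv"),
       monomers = file.path(dir, "monomers.tsv"),
       bond_rules = file.path(dir, "bond_rules.tsv"),
       modifications = file.path(dir, "modifications.tsv"))
}

toy_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb))
      kb <<- load_knowledge_base(write_toy_kb(), G = 8, K = 2,
                                 n_modifications = 2, n_secondary = 3)
    kb
  }
})

# monoisotopic constants used by independent test oracles
M_H <- 1.00782503207
M_C <- 12
M_N <- 14.0030740048
M_O <- 15.9949146196
M_H2O <- 2 * M_H + M_O
M_PROTON <- 1.007276466879
fmass <- function(nC, nH, nN, nO) nC * M_C + nH * M_H + nN * M_N + nO * M_O

# glucose-glucosamine disaccharide and a ribose-extended trisaccharide
# built so the former is an exact terminal truncation of the latter (the
# asymmetric composition keeps the two chain ends mass-distinct)
trunc_fixture <- local({
  fix <- NULL
  function() {
    if (!is.null(fix)) return(fix)
    kb <- pkg_kb()
    bb2 <- assemble_backbones(c("p01", "p03"), kb)
    trunc <- bb2$smiles[1]
    mg <- glycomine:::parse_smiles(trunc)
    rib <- kb$monomers$graph[[match("p06", kb$monomers$id)]]
    # attach ribose via its anomeric O (atom 6) to a free hydroxyl O of
    # the disaccharide (an O with a single heavy neighbour)
    deg <- table(factor(c(mg$bonds$a1, mg$bonds$a2), levels = mg$atoms$id))
    oh <- mg$atoms$id[mg$atoms$elem == "O" & deg == 1][1]
    cmb <- glycomine:::mg_combine(mg, rib)
    u <- cmb$mg
    an <- 6 + cmb$offset
    nb <- c(u$bonds$a2[u$bonds$a1 == an], u$bonds$a1[u$bonds$a2 == an])
    u <- glycomine:::mg_remove_atom(u, an)
    u <- glycomine:::mg_set_bond(u, nb[1], oh, 1L)
    fix <<- list(trunc = trunc, full = canonical_smiles(u))
    fix
  }
})

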