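# End-to-end orchestration and evaluation utilities.

default_config <- function() {
  list(
    window = 10000,          # BGC window extension, bp
    evalue_cutoff = 1e-5,    # HMM hit threshold
    model = "probabilistic", # or "baseline"
    max_monomers = 7,        # largest enumerated multiset
    max_primary = 2,         # primary-monomer instances per set
    max_multiplicity = 3,    # per-monomer copy cap
    top_n = 500,             # ranked sets kept
    assemble_top = 500,      # ranked sets assembled
    relax = FALSE,           # admit gene-free secondary monomers
    max_backbones_per_set = 5000,
    cyclize = FALSE,
    mod_depth = 3,           # applied rules per molecule
    max_mature_per_backbone = 200,
    tol = 0.01,              # fragment tolerance, Da
    precursor_ppm = 10,
    adducts = names(.ADDUCTS),
    search_mode = "standard",
    shift_bounds = c(-300, 300),
    n_decoys = 999,
    p_threshold = 1e-3,
    max_cuts = 2,
    seed = 1
  )
}

parse_set_key <- function(key) {
  parts <- strsplit(key, ",", fixed = TRUE)[[1]]
  ids <- sub(" x .*", "", parts)
  mult <- as.integer(sub(".* x ", "", parts))
  rep(ids, mult)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full genome-to-candidates(-to-matches) pipeline
#'
#' Executes detection, monomer-set ranking, backbone assembly, postassembly
#' modification and (when spectra are given) spectral search, writing every
#' intermediate artifact to `out_dir`. Runs are deterministic given the
#' configuration and seed.
#'
#' @param annotation path to a precomputed annotation TSV (see
#'   [read_annotation_tsv()]), or a GeneHit data.frame; alternatively give
#'   `proteins` + `hmm_file` for live annotation.
#' @param contig_lengths named integer vector of contig lengths.
#' @param out_dir output directory (created if needed).
#' @param spectra optional MGF path or spectra list.
#' @param kb knowledge base (default: packaged catalogs).
#' @param model fitted `monomer_model` (default: fit on the packaged
#'   training pairs).
#' @param proteins,hmm_file optional live-annotation inputs used when
#'   `annotation` is NULL.
#' @param config named list overriding entries of the default
#'   configuration (window, enumeration limits, tolerances, seeds, ...).
#' @return invisibly, a list with the run report (also written as JSON)
#'   and the main tables.
#' @export
run_pipeline <- function(annotation = NULL, contig_lengths, out_dir,
                         spectra = NULL, kb = NULL, model = NULL,
                         proteins = NULL, hmm_file = NULL,
                         config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(kb)) kb <- load_knowledge_base()
  if (is.null(model) && cfg$model == "probabilistic")
    model <- fit_monomer_model(load_training_pairs(kb))

  # 1. annotation
  hits <- if (is.data.frame(annotation)) annotation
          else if (!is.null(annotation)) read_annotation_tsv(annotation)
          else if (!is.null(proteins))
            annotate_proteins(proteins, hmm_file, cfg$evalue_cutoff)
          else stop("provide an annotation table or proteins + hmm_file")

  # 2. regions
  wr <- window_regions(hits, contig_lengths, cfg$window)
  regions <- wr$regions
  regions$bed_start <- regions$start - 1L  # BED export: 0-based half-open
  write_tsv(regions[c("region_id", "contig_id", "bed_start", "end",
                      "n_hits")], file.path(out_dir, "regions.bed"))
  write_tsv(regions[c("region_id", "contig_id", "start", "end", "n_hits")],
            file.path(out_dir, "regions.tsv"))

  # 3. presence vectors
  pres_rows <- list(); pvecs <- list()
  for (rid in regions$region_id) {
    pv <- presence_vector(wr$hits[wr$hits$region_id == rid, ], kb)
    pvecs[[rid]] <- pv
    pres_rows[[rid]] <- data.frame(region_id = rid,
                                   gene_class_id = names(pv),
                                   present = as.integer(pv))
  }
  presence <- if (length(pres_rows)) do.call(rbind, pres_rows)
              else data.frame(region_id = character(),
                              gene_class_id = character(),
                              present = integer())
  rownames(presence) <- NULL
  write_tsv(presence, file.path(out_dir, "presence.tsv"))

  # 4. ranked monomer sets
  ranked_all <- list()
  for (rid in regions$region_id) {
    rs <- enumerate_ranked_sets(
      pvecs[[rid]], kb,
      params = if (cfg$model == "probabilistic") model else NULL,
      model = cfg$model, max_monomers = cfg$max_monomers,
      max_primary = cfg$max_primary,
      max_multiplicity = cfg$max_multiplicity, top_n = cfg$top_n,
      relax = cfg$relax)
    if (nrow(rs)) ranked_all[[rid]] <- cbind(region_id = rid, rs)
  }
  ranked <- if (length(ranked_all)) do.call(rbind, ranked_all)
            else data.frame(region_id = character(), rank = integer(),
                            monomers = character())
  rownames(ranked) <- NULL
  write_tsv(ranked, file.path(out_dir, "ranked_sets.tsv"))

  # 5-6. assembly + modifications -> candidate CSV
  cand_rows <- list()
  for (rid in if (nrow(regions)) regions$region_id else character()) {
    rr <- ranked[ranked$region_id == rid, , drop = FALSE]
    act <- active_rules(kb, pvecs[[rid]])
    for (i in seq_len(min(nrow(rr), cfg$assemble_top))) {
      ids <- parse_set_key(rr$monomers[i])
      bb <- assemble_backbones(ids, kb,
                               max_backbones = cfg$max_backbones_per_set,
                               cyclize = cfg$cyclize)
      for (j in seq_len(nrow(bb))) {
        mat <- enumerate_mature(bb$smiles[j], kb, act,
                                depth = cfg$mod_depth,
                                max_candidates = cfg$max_mature_per_backbone)
        mat <- cbind(region_id = rid, set_rank = rr$rank[i],
                     backbone_id = paste0(rid, ":", rr$rank[i], ":",
                                          bb$backbone_id[j]), mat)
        cand_rows[[length(cand_rows) + 1L]] <- mat
      }
    }
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows)
                else data.frame(region_id = character(),
                                set_rank = integer(),
                                backbone_id = character(),
                                smiles = character(),
                                monoisotopic_mass = numeric(),
                                applied_rules = character(),
                                n_mods = integer())
  # one row per distinct structure: keep the best (lowest) set rank
  candidates <- candidates[order(candidates$set_rank,
                                 candidates$backbone_id,
                                 candidates$smiles), , drop = FALSE]
  candidates <- candidates[!duplicated(candidates[c("region_id", "smiles")]),
                           , drop = FALSE]
  candidates <- cbind(candidate_id = sprintf("cand%05d",
                                             seq_len(nrow(candidates))),
                      candidates)
  rownames(candidates) <- NULL
  utils::write.csv(candidates[c("candidate_id", "region_id", "set_rank",
                                "backbone_id", "smiles",
                                "monoisotopic_mass", "applied_rules")],
                   file.path(out_dir, "candidates.csv"), row.names = FALSE,
                   quote = FALSE)

  # 7. spectral search
  matches <- NULL
  if (!is.null(spectra) && nrow(candidates)) {
    matches <- search_spectra(candidates, spectra, tol = cfg$tol,
                              precursor_ppm = cfg$precursor_ppm,
                              adducts = cfg$adducts,
                              mode = cfg$search_mode,
                              shift_bounds = cfg$shift_bounds,
                              n_decoys = cfg$n_decoys,
                              p_threshold = cfg$p_threshold,
                              max_cuts = cfg$max_cuts, seed = cfg$seed)
    write_tsv(matches, file.path(out_dir, "matches.tsv"))
  }

  report <- list(
    config = cfg,
    counts = list(hits = nrow(hits), regions = nrow(regions),
                  ranked_sets = nrow(ranked),
                  candidates = nrow(candidates),
                  matches = if (is.null(matches)) 0L else nrow(matches))
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, hits = hits, regions = regions,
                 presence = presence, ranked = ranked,
                 candidates = candidates, matches = matches))
}

# --- Tanimoto benchmarking ------------------------------------------------

# linear-path substructure features up to max_len atoms; each feature is
# the lexicographically smaller of the forward/reverse element-bond string
path_features <- function(mg, max_len = 7) {
  n <- nrow(mg$atoms)
  adj <- vector("list", n)
  idx <- setNames(seq_len(n), mg$atoms$id)
  if (nrow(mg$bonds)) for (k in seq_len(nrow(mg$bonds))) {
    i <- idx[as.character(mg$bonds$a1[k])]
    j <- idx[as.character(mg$bonds$a2[k])]
    o <- mg$bonds$order[k]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  elems <- mg$atoms$elem
  feats <- new.env(hash = TRUE)
  emit <- function(lab) {
    rev_lab <- paste(rev(strsplit(lab, "|", fixed = TRUE)[[1]]),
                     collapse = "|")
    assign(min(lab, rev_lab), TRUE, envir = feats)
  }
  dfs <- function(v, visited, lab, depth) {
    emit(lab)
    if (depth == max_len) return()
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]
      if (visited[w]) next
      visited2 <- visited; visited2[w] <- TRUE
      dfs(w, visited2, paste(lab, nb[r, 2], elems[w], sep = "|"),
          depth + 1L)
    }
  }
  for (v in seq_len(n)) {
    visited <- logical(n); visited[v] <- TRUE
    dfs(v, visited, elems[v], 1L)
  }
  ls(envir = feats)
}

#' Tanimoto similarity of two structures
#'
#' Ratio of shared binary substructure features to the features present in
#' either compound, over linear-path features up to `max_len` atoms.
#' Tanimoto values depend on the fingerprint; the path length is therefore
#' part of the reported configuration.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @param max_len maximum path length in atoms (default 7).
#' @return similarity in [0, 1]; 1 for identical 2D structures.
#' @export
tanimoto <- function(smiles_a, smiles_b, max_len = 7) {
  fa <- path_features(parse_smiles(smiles_a), max_len)
  fb <- path_features(parse_smiles(smiles_b), max_len)
  if (!length(fa) && !length(fb)) return(1)
  length(intersect(fa, fb)) / length(union(fa, fb))
}

#' Benchmark predicted candidate sets against truth structures
#'
#' For each truth structure, the best Tanimoto similarity over its
#' candidate set is recorded (0 for an empty set), and the number of
#' truths at or above each threshold is reported.
#'
#' @param candidate_sets named list; one character vector of candidate
#'   SMILES per truth structure.
#' @param truths named character vector of truth SMILES (names must match
#'   `candidate_sets`).
#' @param thresholds similarity thresholds (default 0.7, 0.85, 0.95, 1).
#' @param max_len fingerprint path length (default 7).
#' @return list with `per_molecule` (molecule, best_similarity) and
#'   `counts` (threshold, n_correct).
#' @export
benchmark_report <- function(candidate_sets, truths,
                             thresholds = c(0.7, 0.85, 0.95, 1.0),
                             max_len = 7) {
  stopifnot(all(names(truths) %in% names(candidate_sets)))
  best <- vapply(names(truths), function(nm) {
    cands <- candidate_sets[[nm]]
    if (!length(cands)) return(0)
    max(vapply(cands, function(s) tanimoto(truths[[nm]], s, max_len), 0))
  }, 0)
  list(
    per_molecule = data.frame(molecule = names(truths),
                              best_similarity = unname(best)),
    counts = data.frame(threshold = thresholds,
                        n_correct = vapply(thresholds, function(t)
                          sum(best >= t), 0L))
  )
}
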