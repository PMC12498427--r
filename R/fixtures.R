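# Synthetic fixture generators.
#
# Everything the test suite and worked examples need is generated in code
# from explicit seeds: training pairs drawn from known (alpha, beta,
# gamma), toy genomes with implanted gene cassettes (plus toy profile HMMs
# built with hmmbuild so the live annotation path can be exercised), and
# noisy spectra derived from known structures with truth metadata embedded
# in the MGF title. Identical (specification, seed) inputs give
# byte-identical outputs.

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulate training pairs from known model parameters
#'
#' For each pair a BGC presence vector b is drawn (each class present with
#' probability `b_prob`), gene labels g_i | b_i follow the four-case table
#' with the true (alpha, beta), and primary-monomer flags m_j are
#' Bernoulli(gamma).
#'
#' @param n_pairs number of (saccharide, BGC) pairs.
#' @param G,K dimensions.
#' @param alpha,beta,gamma true parameters.
#' @param b_prob marginal presence probability of a gene class in a BGC
#'   (default 0.3).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of pairs, each with binary vectors `g`, `m`, `b`.
#' @export
make_training_pairs <- function(n_pairs, G = 50, K = 6, alpha = 0.9,
                                beta = 0.05, gamma = 0.3, b_prob = 0.3,
                                seed = 1) {
  stopifnot(n_pairs >= 1, !is.null(seed))
  with_seed(seed, lapply(seq_len(n_pairs), function(i) {
    b <- stats::rbinom(G, 1, b_prob)
    g <- ifelse(b == 1, stats::rbinom(G, 1, alpha),
                        stats::rbinom(G, 1, beta))
    m <- stats::rbinom(K, 1, gamma)
    list(g = g, m = m, b = b)
  }))
}

#' Load the packaged curated training pairs
#'
#' A reconstruction of a 20-molecule benchmark training set (one row per
#' known saccharide with its monomer composition and the gene classes
#' annotated in its BGC), mapped onto the packaged catalog. The g vector is
#' derived from the molecule's secondary monomers, m from its primary
#' monomers, b from the annotated class list.
#'
#' @param kb a `glyco_kb`.
#' @param path TSV path (defaults to the packaged table).
#' @return list of training pairs suitable for [fit_monomer_model()].
#' @export
load_training_pairs <- function(kb, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kb", "training_pairs.tsv",
                        package = "glycomine")
  df <- read_catalog(path)
  classes <- kb$gene_classes$id
  prim <- kb$monomers$id[kb$monomers$is_primary]
  lapply(seq_len(nrow(df)), function(i) {
    monomers <- split_ids(df$monomer_ids[i])
    sv <- saccharide_vector(kb, monomers)
    present <- split_ids(df$present_classes[i])
    bad <- setdiff(present, classes)
    if (length(bad)) stop("training pair ", df$pair_id[i],
                          ": unknown class ", paste(bad, collapse = ","))
    list(g = sv$g, m = sv$m,
         b = setNames(as.integer(classes %in% present), classes),
         molecule = df$molecule[i], monomers = monomers)
  })
}

# random peptide of given length (uniform over 20 amino acids)
random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

#' Build toy profile HMMs for a set of gene classes
#'
#' For each class a random consensus peptide is drawn and a small mutated
#' alignment is built into a profile with hmmbuild (HMMER 3). The profile
#' NAME is the class id. Used to exercise the live annotation path on
#' synthetic genomes.
#'
#' @param class_ids gene-class ids.
#' @param dir output directory.
#' @param seed RNG seed.
#' @param length consensus length (default 120).
#' @param n_seqs alignment depth (default 8).
#' @param mut_rate per-residue substitution rate in the alignment copies.
#' @return list with `hmm_file` (concatenated profiles) and `consensus`
#'   (named character vector of consensus peptides).
#' @export
make_toy_profiles <- function(class_ids, dir = tempfile("profiles"),
                              seed = 1, length = 120, n_seqs = 8,
                              mut_rate = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hmms <- character()
  consensus <- character()
  with_seed(seed, for (cid in class_ids) {
    cons <- random_peptide(length)
    consensus[cid] <- cons
    seqs <- vapply(seq_len(n_seqs), function(k) {
      v <- strsplit(cons, "")[[1]]
      flip <- stats::runif(length) < mut_rate
      v[flip] <- sample(aa, sum(flip), replace = TRUE)
      paste(v, collapse = "")
    }, "")
    afa <- file.path(dir, paste0(cid, ".afa"))
    writeLines(c(rbind(paste0(">", cid, "_", seq_len(n_seqs)), seqs)), afa)
    hmm <- file.path(dir, paste0(cid, ".hmm"))
    status <- system2("hmmbuild",
                      c("-n", cid, "--amino", shQuote(hmm), shQuote(afa)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0) stop("hmmbuild failed for ", cid)
    hmms <- c(hmms, hmm)
  })
  combined <- file.path(dir, "profiles.hmm")
  writeLines(unlist(lapply(hmms, readLines)), combined)
  list(hmm_file = combined, consensus = consensus)
}

#' Generate a toy genome with implanted gene cassettes
#'
#' Writes a protein FASTA whose headers carry genomic coordinates, a
#' precomputed annotation TSV (the HMM-free bypass) and a truth table.
#' Implanted proteins are the designated class consensus peptides (or
#' deterministic stand-ins when no profiles are given) placed at the
#' planned loci among random-composition filler proteins.
#'
#' @param implants data.frame with columns `gene_class_id`, `contig_id`,
#'   `start`, `end`, `strand`.
#' @param contig_lengths named integer vector.
#' @param dir output directory.
#' @param n_filler random filler proteins per contig (default 5).
#' @param consensus optional named peptide vector from
#'   [make_toy_profiles()]; used as implant sequences.
#' @param seed RNG seed.
#' @return list with `proteins` (FASTA path), `annotation` (TSV path),
#'   `truth` (the implant table), `contig_lengths`.
#' @export
make_toy_genome <- function(implants, contig_lengths,
                            dir = tempfile("genome"), n_filler = 5,
                            consensus = NULL, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    headers <- character(); seqs <- character()
    ann <- NULL
    if (nrow(implants)) for (i in seq_len(nrow(implants))) {
      im <- implants[i, ]
      pid <- sprintf("implant_%02d", i)
      headers <- c(headers, sprintf("%s contig=%s;start=%d;end=%d;strand=%s",
                                    pid, im$contig_id, im$start, im$end,
                                    im$strand))
      seqs <- c(seqs, if (!is.null(consensus) &&
                          im$gene_class_id %in% names(consensus))
        consensus[[im$gene_class_id]] else random_peptide(120))
      ann <- rbind(ann, data.frame(
        protein_id = pid, gene_class_id = im$gene_class_id, evalue = 1e-30,
        contig_id = im$contig_id, start = im$start, end = im$end,
        strand = im$strand, stringsAsFactors = FALSE))
    }
    for (ctg in names(contig_lengths)) for (k in seq_len(n_filler)) {
      pid <- sprintf("filler_%s_%02d", ctg, k)
      pos <- sample.int(max(1L, contig_lengths[[ctg]] - 400L), 1)
      headers <- c(headers,
                   sprintf("%s contig=%s;start=%d;end=%d;strand=+",
                           pid, ctg, pos, pos + 299L))
      seqs <- c(seqs, random_peptide(100))
    }
    fasta <- file.path(dir, "proteins.faa")
    writeLines(c(rbind(paste0(">", headers), seqs)), fasta)
    tsv <- file.path(dir, "annotation.tsv")
    if (is.null(ann))
      ann <- data.frame(protein_id = character(),
                        gene_class_id = character(), evalue = numeric(),
                        contig_id = character(), start = integer(),
                        end = integer(), strand = character())
    utils::write.table(ann, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(proteins = fasta, annotation = tsv, truth = implants,
         contig_lengths = contig_lengths)
  })
}

#' Generate a synthetic MS/MS spectrum from a structure
#'
#' Theoretical fragments are computed, a seeded dropout applied, surviving
#' peaks jittered uniformly within the match tolerance, uniform random
#' noise peaks added, and an optional global mass shift applied to all
#' peaks. Truth metadata is embedded in the spectrum title.
#'
#' @param structure SMILES string.
#' @param adduct adduct label (default `"[M+H]+"`).
#' @param dropout fragment dropout probability (default 0).
#' @param n_noise number of uniform noise peaks (default 0).
#' @param global_shift mass shift applied to all peaks in Da (default 0).
#' @param jitter peak jitter half-width in Da (default 0.002).
#' @param tol match tolerance the fixture targets (default 0.01).
#' @param max_cuts fragmentation depth (default 2).
#' @param seed RNG seed.
#' @param spectrum_id title (default auto with truth metadata).
#' @return a spectrum list compatible with [write_mgf()].
#' @export
make_spectrum <- function(structure, adduct = "[M+H]+", dropout = 0,
                          n_noise = 0, global_shift = 0, jitter = 0.002,
                          tol = 0.01, max_cuts = 2, seed = 1,
                          spectrum_id = NULL) {
  stopifnot(jitter < tol)
  theo <- fragment(structure, max_cuts = max_cuts)
  delta <- adduct_delta(adduct)
  with_seed(seed, {
    keep <- stats::runif(nrow(theo)) >= dropout
    mz <- theo$mass[keep] + delta +
      stats::runif(sum(keep), -jitter, jitter)
    if (n_noise > 0) {
      lo <- min(theo$mass) + delta - 20; hi <- max(theo$mass) + delta + 20
      noise <- stats::runif(n_noise, lo, hi)
      # keep noise away from true peaks so planted counts stay exact
      for (k in seq_along(noise)) {
        tries <- 0L
        while (min(abs(noise[k] - (theo$mass + delta))) < 2 * tol &&
               tries < 1000L) {
          noise[k] <- stats::runif(1, lo, hi)
          tries <- tries + 1L
        }
      }
      mz <- c(mz, noise)
    }
    mz <- sort(mz + global_shift)
    if (is.null(spectrum_id))
      spectrum_id <- sprintf(
        "synthetic|planted=%d|noise=%d|shift=%.4f|seed=%d",
        sum(keep), n_noise, global_shift, seed)
    list(spectrum_id = spectrum_id,
         precursor_mz = theo$mass[1] + delta + global_shift,
         charge = if (delta < 0) -1L else 1L,
         peaks = data.frame(mz = mz, intensity = rep(100, length(mz))),
         truth = list(n_planted = sum(keep), n_noise = n_noise,
                      shift = global_shift))
  })
}
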