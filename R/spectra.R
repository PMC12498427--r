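# Simplified in-silico fragmentation and spectral matching.
#
# Theoretical spectra are generated by cutting up to `max_cuts` bridge
# bonds (acyclic bonds whose two sides each retain >= 3 heavy atoms, which
# approximates inter-monomer linkages) and emitting the neutral mass of
# every resulting connected component; freed valences are capped with one
# hydrogen per cut end, which the implicit-hydrogen model performs
# automatically. Scoring is a shared-peak count: experimental peaks matched
# one-to-one (greedy nearest) to adduct-adjusted fragment m/z within a
# tolerance. The variable mode additionally allows one global mass shift:
# every fragment may match at its m/z or its m/z plus the shift, absorbing
# a missing monomer or modification. Significance is an empirical p-value
# against decoy theoretical spectra with uniformly resampled fragment
# masses. This scorer is deliberately simple and fully specified; it is
# not a full fragmentation-graph dereplication engine, and its integer
# scores are not comparable to other tools'.

.ADDUCTS <- c("[M+H]+" = 1.007276466879,
              "[M-H]-" = -1.007276466879,
              "[M+NH3]-" = 16.019272654)

adduct_delta <- function(adduct) {
  if (!adduct %in% names(.ADDUCTS)) stop("unknown adduct label: ", adduct)
  .ADDUCTS[[adduct]]
}

#' Theoretical fragmentation spectrum of a structure
#'
#' @param structure SMILES string or internal molgraph.
#' @param max_cuts maximum number of simultaneously cleaved bridge bonds
#'   (default 2).
#' @param min_side minimum heavy-atom count on each side for a bond to
#'   count as an inter-unit bridge (default 3).
#' @return data.frame with columns `mass` (neutral Da), `formula`,
#'   `n_cuts`, deduplicated by (formula, mass); the 0-cut row is the intact
#'   molecule.
#' @export
fragment <- function(structure, max_cuts = 2, min_side = 3) {
  mg <- if (inherits(structure, "molgraph")) structure
        else parse_smiles(structure)
  g <- mg_to_igraph(mg)
  bridges <- integer()
  if (nrow(mg$bonds)) {
    br <- igraph::bridges(g)
    for (e in br) {
      g2 <- igraph::delete_edges(g, e)
      comp <- igraph::components(g2)
      if (min(comp$csize) >= min_side) bridges <- c(bridges, e)
    }
  }
  frag_key <- new.env(hash = TRUE)
  rows <- list()
  atom_sets <- list()
  note <- function(sub_ids, ncuts) {
    sub <- mg
    sub$atoms <- sub$atoms[sub$atoms$id %in% sub_ids, , drop = FALSE]
    sub$bonds <- sub$bonds[sub$bonds$a1 %in% sub_ids &
                             sub$bonds$a2 %in% sub_ids, , drop = FALSE]
    f <- mg_formula(sub)
    key <- paste(names(f), f, collapse = "")
    if (exists(key, envir = frag_key, inherits = FALSE)) return()
    assign(key, TRUE, envir = frag_key)
    rows[[length(rows) + 1L]] <<- data.frame(
      mass = mg_mass(sub), formula = key, n_cuts = ncuts,
      stringsAsFactors = FALSE)
    atom_sets[[length(atom_sets) + 1L]] <<- sort(sub_ids)
  }
  cut_sets <- list(integer())
  if (length(bridges) && max_cuts >= 1) {
    cut_sets <- c(cut_sets, lapply(bridges, function(b) b))
    if (max_cuts >= 2 && length(bridges) >= 2) {
      cmb <- utils::combn(bridges, 2, simplify = FALSE)
      cut_sets <- c(cut_sets, cmb)
    }
    if (max_cuts >= 3 && length(bridges) >= 3)
      cut_sets <- c(cut_sets,
                    utils::combn(bridges, 3, simplify = FALSE))
  }
  for (cs in cut_sets) {
    # remove the cut bonds from the bond table, then take components; the
    # recount of implicit hydrogens caps each cut end with one H
    g2 <- if (length(cs)) igraph::delete_edges(g, cs) else g
    comp <- igraph::components(g2)
    for (k in seq_len(comp$no))
      note(mg$atoms$id[comp$membership == k], length(cs))
  }
  res <- do.call(rbind, rows)
  res$atoms <- atom_sets
  ord <- order(-res$mass)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Shared-peak score of a theoretical spectrum against an experimental one
#'
#' Greedy one-to-one nearest-mass matching: the number of experimental
#' peaks matched by an adduct-adjusted theoretical fragment m/z within
#' `tol` Da.
#'
#' @param theo fragment table from [fragment()] (or numeric fragment
#'   masses).
#' @param exp an experimental spectrum (list with `peaks` data.frame
#'   holding `mz`), or a data.frame of peaks.
#' @param tol fragment match tolerance in Da (default 0.01).
#' @param adduct adduct label (default `"[M+H]+"`).
#' @return integer score.
#' @export
score_match <- function(theo, exp, tol = 0.01, adduct = "[M+H]+") {
  stopifnot(tol > 0)
  masses <- if (is.data.frame(theo)) theo$mass else as.numeric(theo)
  mz_theo <- masses + adduct_delta(adduct)
  peaks <- if (is.data.frame(exp)) exp else exp$peaks
  if (!NROW(peaks) || !length(mz_theo)) return(0L)
  greedy_match_count(mz_theo, peaks$mz, tol)
}

greedy_match_count <- function(theo_mz, exp_mz, tol) {
  pairs <- NULL
  for (i in seq_along(theo_mz)) {
    d <- abs(exp_mz - theo_mz[i])
    j <- which(d <= tol)
    if (length(j))
      pairs <- rbind(pairs, cbind(i = i, j = j, d = d[j]))
  }
  if (is.null(pairs)) return(0L)
  pairs <- pairs[order(pairs[, "d"]), , drop = FALSE]
  used_i <- logical(length(theo_mz)); used_j <- logical(length(exp_mz))
  n <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, "i"]; j <- pairs[k, "j"]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    n <- n + 1L
  }
  n
}

#' Variable (mass-shift-tolerant) match score
#'
#' Maximizes the shared-peak score over a single global mass shift applied
#' to the connected sub-portion of fragments containing a designated cut
#' side: for each bridge-cut side of the molecule (each 1-cut fragment,
#' plus the whole molecule), the fragments containing that side are
#' shifted by s while the remaining fragments match unshifted. Candidate
#' shifts are data-driven (peak minus shiftable-fragment differences
#' within the bounds, smallest magnitude first); shift 0 is always
#' included, so the variable score is at least the standard score. This
#' absorbs a missing or extra monomer or modification.
#'
#' @param theo fragment table from [fragment()] (with atom provenance), or
#'   numeric fragment masses (then the shift applies to all fragments).
#' @param exp,tol,adduct as in [score_match()].
#' @param shift_bounds numeric length-2 vector, allowed shift range in Da
#'   (default c(-500, 500)); `c(0, 0)` degenerates to [score_match()].
#' @param indicators optional logical matrix (fragments x sides) overriding
#'   the shiftable-fragment sets (used for decoy spectra that must share
#'   the real candidate's cut structure).
#' @return list with `score` and `shift` (the maximizing shift; 0 on ties).
#' @export
variable_score <- function(theo, exp, tol = 0.01, adduct = "[M+H]+",
                           shift_bounds = c(-500, 500), indicators = NULL) {
  masses <- if (is.data.frame(theo)) theo$mass else as.numeric(theo)
  mz_theo <- masses + adduct_delta(adduct)
  peaks <- if (is.data.frame(exp)) exp else exp$peaks
  base <- score_match(theo, exp, tol, adduct)
  if (!NROW(peaks) || identical(as.numeric(shift_bounds), c(0, 0)))
    return(list(score = base, shift = 0))
  if (is.null(indicators)) indicators <- shift_indicators(theo)
  best <- list(score = base, shift = 0)
  for (side in seq_len(ncol(indicators))) {
    ind <- indicators[, side]
    if (!any(ind)) next
    diffs <- as.vector(outer(peaks$mz, mz_theo[ind], "-"))
    diffs <- diffs[diffs >= shift_bounds[1] & diffs <= shift_bounds[2] &
                     abs(diffs) > tol]
    if (!length(diffs)) next
    cand <- unique(round(diffs / tol) * tol)
    cand <- cand[order(abs(cand))]   # prefer the smallest shift on ties
    for (s in cand) {
      sc <- greedy_match_count(mz_theo + s * ind, peaks$mz, tol)
      if (sc > best$score) best <- list(score = sc, shift = s)
    }
  }
  best
}

# fragments x sides indicator matrix: one side per 1-cut fragment (its
# atom set designates one side of one bridge bond) plus the whole molecule
shift_indicators <- function(theo) {
  n <- if (is.data.frame(theo)) nrow(theo) else length(theo)
  if (!is.data.frame(theo) || is.null(theo$atoms))
    return(matrix(TRUE, nrow = n, ncol = 1))
  sides <- theo$atoms[theo$n_cuts == 1]
  ind <- vapply(sides, function(S)
    vapply(theo$atoms, function(a) all(S %in% a), TRUE),
    logical(n))
  ind <- matrix(ind, nrow = n)
  cbind(matrix(TRUE, nrow = n, ncol = 1), ind)
}

#' Decoy-based empirical p-value of a match score
#'
#' Decoy theoretical spectra preserve the fragment count but resample
#' fragment masses uniformly over the observed theoretical mass range; the
#' p-value is (1 + #\{decoys scoring >= observed\}) / (n_decoys + 1).
#'
#' @param observed_score observed shared-peak score.
#' @param theo fragment table (or numeric masses) of the candidate.
#' @param exp experimental spectrum.
#' @param tol,adduct as in [score_match()].
#' @param n_decoys number of decoys (default 999; must be >= 99).
#' @param seed RNG seed for the decoy draw.
#' @param variable use the variable scorer for decoys too (default FALSE).
#' @param shift_bounds passed to [variable_score()] when `variable`.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed_score, theo, exp, tol = 0.01,
                             adduct = "[M+H]+", n_decoys = 999,
                             seed = 1, variable = FALSE,
                             shift_bounds = c(-500, 500)) {
  if (n_decoys < 99) stop("use at least 99 decoys")
  masses <- if (is.data.frame(theo)) theo$mass else as.numeric(theo)
  rng <- range(masses)
  nfrag <- length(masses)
  ind <- if (variable) shift_indicators(theo)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ge <- 0L
  for (k in seq_len(n_decoys)) {
    decoy <- stats::runif(nfrag, rng[1], rng[2])
    sc <- if (variable)
      variable_score(decoy, exp, tol, adduct, shift_bounds,
                     indicators = ind)$score
    else score_match(decoy, exp, tol, adduct)
    if (sc >= observed_score) ge <- ge + 1L
  }
  (1 + ge) / (n_decoys + 1)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- MGF I/O --------------------------------------------------------------

#' Read an MGF spectra file
#'
#' @param path MGF file.
#' @return list of spectra; each a list with `spectrum_id`, `precursor_mz`,
#'   `charge` (signed integer or NA) and `peaks` (mz, intensity), peaks
#'   sorted by mz.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("spectra file not found: ", path)
  lines <- readLines(path)
  spectra <- list()
  cur <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      cur <- list(spectrum_id = NA_character_, precursor_mz = NA_real_,
                  charge = NA_integer_, mz = numeric(), int = numeric())
    } else if (ln == "END IONS") {
      o <- order(cur$mz)
      spectra[[length(spectra) + 1L]] <- list(
        spectrum_id = cur$spectrum_id, precursor_mz = cur$precursor_mz,
        charge = cur$charge,
        peaks = data.frame(mz = cur$mz[o], intensity = cur$int[o]))
      cur <- NULL
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(cur)) next
      key <- sub("=.*", "", ln); val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") cur$spectrum_id <- val
      else if (key == "PEPMASS")
        cur$precursor_mz <- as.numeric(strsplit(val, "[[:space:]]+")[[1]][1])
      else if (key == "CHARGE") {
        sign <- if (grepl("-", val, fixed = TRUE)) -1L else 1L
        cur$charge <- sign * as.integer(gsub("[^0-9]", "", val))
      }
    } else if (!is.null(cur)) {
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      cur$mz <- c(cur$mz, as.numeric(tok[1]))
      cur$int <- c(cur$int, if (length(tok) > 1) as.numeric(tok[2]) else 1)
    }
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra list of spectra as returned by [read_mgf()].
#' @param path output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$charge))
      writeLines(sprintf("CHARGE=%d%s", abs(sp$charge),
                         if (sp$charge < 0) "-" else "+"), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.2f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Search candidate structures against tandem spectra
#'
#' For each spectrum and adduct hypothesis, candidates whose neutral mass
#' lies within the precursor tolerance (or within the shift bounds in
#' variable mode) are scored and assigned decoy p-values; matches passing
#' the p-value threshold are returned.
#'
#' @param candidates data.frame with columns `candidate_id`, `smiles`,
#'   `monoisotopic_mass`.
#' @param spectra list of spectra (see [read_mgf()]) or an MGF path.
#' @param tol fragment tolerance in Da (default 0.01).
#' @param precursor_ppm precursor tolerance in ppm (default 10).
#' @param adducts adduct hypothesis set (default all packaged adducts).
#' @param mode `"standard"` or `"variable"`.
#' @param shift_bounds variable-mode shift range in Da.
#' @param n_decoys decoys per match for p-values (default 999).
#' @param p_threshold reporting threshold (default 1e-3).
#' @param max_cuts fragmentation depth (default 2).
#' @param seed decoy RNG seed.
#' @return data.frame (spectrum_id, candidate_id, smiles, adduct, shift,
#'   score, p_value), ordered by p-value then decreasing score.
#' @export
search_spectra <- function(candidates, spectra, tol = 0.01,
                           precursor_ppm = 10,
                           adducts = names(.ADDUCTS),
                           mode = c("standard", "variable"),
                           shift_bounds = c(-300, 300), n_decoys = 999,
                           p_threshold = 1e-3, max_cuts = 2, seed = 1) {
  mode <- match.arg(mode)
  if (is.character(spectra)) spectra <- read_mgf(spectra)
  out <- list()
  if (!nrow(candidates) || !length(spectra))
    return(data.frame(spectrum_id = character(), candidate_id = character(),
                      smiles = character(), adduct = character(),
                      shift = numeric(), score = integer(),
                      p_value = numeric()))
  frag_cache <- new.env(hash = TRUE)
  get_frags <- function(smi) {
    if (!exists(smi, envir = frag_cache, inherits = FALSE))
      assign(smi, fragment(smi, max_cuts = max_cuts), envir = frag_cache)
    get(smi, envir = frag_cache)
  }
  for (sp in spectra) {
    for (ad in adducts) {
      neutral <- sp$precursor_mz - adduct_delta(ad)
      ptol <- neutral * precursor_ppm * 1e-6
      dm <- neutral - candidates$monoisotopic_mass
      sel <- if (mode == "standard") which(abs(dm) <= ptol)
             else which(dm >= shift_bounds[1] - ptol &
                        dm <= shift_bounds[2] + ptol)
      for (ci in sel) {
        theo <- get_frags(candidates$smiles[ci])
        if (mode == "standard") {
          sc <- score_match(theo, sp, tol, ad)
          sh <- 0
        } else {
          vs <- variable_score(theo, sp, tol, ad, shift_bounds)
          sc <- vs$score; sh <- vs$shift
        }
        if (sc == 0) next
        p <- empirical_pvalue(sc, theo, sp, tol, ad, n_decoys = n_decoys,
                              seed = seed + ci,
                              variable = (mode == "variable"),
                              shift_bounds = shift_bounds)
        if (p <= p_threshold)
          out[[length(out) + 1L]] <- data.frame(
            spectrum_id = sp$spectrum_id,
            candidate_id = candidates$candidate_id[ci],
            smiles = candidates$smiles[ci], adduct = ad, shift = sh,
            score = sc, p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(spectrum_id = character(), candidate_id = character(),
                      smiles = character(), adduct = character(),
                      shift = numeric(), score = integer(),
                      p_value = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$p_value, -res$score, res$candidate_id), ]
  rownames(res) <- NULL
  res
}
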