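# In-silico fragmentation, scoring, variable search and p-values.

test_that("a single monomer yields only its intact mass", {
  fr <- fragment("OCC1OC(O)C(O)C(O)C1O")
  expect_equal(nrow(fr), 1)
  expect_equal(fr$mass, 180.06339, tolerance = 1e-4)
  expect_equal(fr$n_cuts, 0)
})

test_that("fragment enumeration matches a brute-force bond-subset oracle", {
  kb <- pkg_kb()
  bb <- suppressWarnings(assemble_backbones(c("p01", "p01", "p01"), kb,
                                            max_backbones = 5))
  smi <- bb$smiles[1]
  fr <- fragment(smi, max_cuts = 2)
  # oracle: plain BFS components over all <= 2-subsets of qualifying bonds,
  # with masses from atom counting plus valence-rule hydrogen capping
  mg <- glycomine:::parse_smiles(smi)
  val <- c(C = 4, N = 3, O = 2)
  comp_of <- function(bonds) {
    ids <- mg$atoms$id
    parent <- setNames(ids, ids)
    find <- function(x) { while (parent[[as.character(x)]] != x)
      x <- parent[[as.character(x)]]; x }
    if (nrow(bonds)) for (k in seq_len(nrow(bonds)))
      parent[as.character(find(bonds$a1[k]))] <- find(bonds$a2[k])
    split(ids, vapply(ids, find, 0))
  }
  bfs_mass <- function(ids, bonds) {
    el <- mg$atoms$elem[match(ids, mg$atoms$id)]
    bsum <- setNames(numeric(length(ids)), ids)
    sub <- bonds[bonds$a1 %in% ids & bonds$a2 %in% ids, , drop = FALSE]
    if (nrow(sub)) for (k in seq_len(nrow(sub))) {
      bsum[as.character(sub$a1[k])] <- bsum[as.character(sub$a1[k])] +
        sub$order[k]
      bsum[as.character(sub$a2[k])] <- bsum[as.character(sub$a2[k])] +
        sub$order[k]
    }
    nH <- sum(pmax(0, val[el] - bsum))
    sum(c(C = M_C, N = M_N, O = M_O)[el]) + nH * M_H
  }
  # qualifying bridges: acyclic bonds with >= 3 heavy atoms on both sides
  is_bridge <- vapply(seq_len(nrow(mg$bonds)), function(k) {
    rest <- mg$bonds[-k, , drop = FALSE]
    comps <- comp_of(rest)
    length(comps) == 2 && min(lengths(comps)) >= 3
  }, TRUE)
  br <- which(is_bridge)
  subsets <- c(list(integer()), as.list(br),
               if (length(br) >= 2) utils::combn(br, 2, simplify = FALSE))
  oracle <- c()
  for (cs in subsets) {
    comps <- comp_of(mg$bonds[setdiff(seq_len(nrow(mg$bonds)), cs), ,
                              drop = FALSE])
    for (ids in comps)
      oracle <- c(oracle, bfs_mass(ids, mg$bonds[setdiff(
        seq_len(nrow(mg$bonds)), cs), , drop = FALSE]))
  }
  oracle <- sort(unique(round(oracle, 5)), decreasing = TRUE)
  expect_equal(sort(unique(round(fr$mass, 5)), decreasing = TRUE), oracle,
               tolerance = 1e-5)
  # containment: every fragment mass <= intact, intact present
  expect_true(all(fr$mass <= fr$mass[1] + 1e-9))
  expect_equal(fr$mass[1], monoisotopic_mass(smi), tolerance = 1e-6)
})

test_that("self-matches score the full peak count and noise scores zero", {
  fix <- trunc_fixture()
  sp <- make_spectrum(fix$trunc, seed = 4)
  theo <- fragment(fix$trunc)
  expect_equal(score_match(theo, sp), nrow(sp$peaks))
  # peaks far from every fragment
  off <- sp; off$peaks$mz <- off$peaks$mz + 5
  expect_equal(score_match(theo, off), 0)
  # planted 6 + 4 noise peaks at tol 0.01
  sp6 <- make_spectrum(fix$trunc, dropout = 0.4, n_noise = 4, seed = 8)
  expect_equal(score_match(fragment(fix$trunc), sp6, tol = 0.01),
               sp6$truth$n_planted)
})

test_that("variable search degenerates to and dominates standard search", {
  fix <- trunc_fixture()
  theo <- fragment(fix$full)
  set.seed(31)
  for (k in 1:30) {
    peaks <- data.frame(mz = runif(12, 150, 600), intensity = 1)
    sp <- list(spectrum_id = "r", precursor_mz = 500, charge = 1L,
               peaks = peaks[order(peaks$mz), ])
    std <- score_match(theo, sp)
    expect_identical(variable_score(theo, sp, shift_bounds = c(0, 0)),
                     list(score = std, shift = 0))
    expect_gte(variable_score(theo, sp)$score, std)
  }
})

test_that("variable search recovers a terminal-monomer-loss shift", {
  fix <- trunc_fixture()
  sp <- make_spectrum(fix$trunc, seed = 3, max_cuts = 1)
  theo_full <- fragment(fix$full, max_cuts = 1)
  self_score <- score_match(fragment(fix$trunc, max_cuts = 1), sp)
  vs <- variable_score(theo_full, sp)
  expect_equal(vs$score, self_score)
  # shift = -(ribose mass - H2O)
  expect_equal(vs$shift, -(150.05282 - M_H2O), tolerance = 0.02)
  expect_gt(vs$score, score_match(theo_full, sp))
})

test_that("empirical p-values separate self-matches from noise", {
  fix <- trunc_fixture()
  theo <- fragment(fix$trunc)
  sp <- make_spectrum(fix$trunc, seed = 5)
  obs <- score_match(theo, sp)
  p <- empirical_pvalue(obs, theo, sp, n_decoys = 999, seed = 11)
  expect_lte(p, 1e-3)
  expect_equal(empirical_pvalue(0, theo, sp, n_decoys = 999, seed = 11), 1,
               tolerance = 1e-3)
})

test_that("p-values are valid and non-degenerate under the decoy null", {
  fix <- trunc_fixture()
  theo <- fragment(fix$trunc)
  # a wide tolerance makes null scores vary, so the p-value distribution
  # is informative rather than concentrated at 1
  set.seed(77)
  ps <- vapply(1:200, function(k) {
    peaks <- data.frame(mz = runif(30, min(theo$mass), max(theo$mass) + 1),
                        intensity = 1)
    sp <- list(spectrum_id = "null", precursor_mz = 400, charge = 1L,
               peaks = peaks[order(peaks$mz), ])
    obs <- score_match(theo, sp, tol = 1)
    empirical_pvalue(obs, theo, sp, tol = 1, n_decoys = 199,
                     seed = 1000 + k)
  }, 0)
  # conservative validity: P(p <= t) <= t + 1/(decoys+1) up to Monte Carlo
  for (t in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= t), t + 1 / 200 + 3 * sqrt(t * (1 - t) / 200))
  # approximate uniformity: spread over (0, 1], not a point mass
  expect_gt(stats::sd(ps), 0.15)
  expect_lt(min(ps), 0.2)
  expect_gt(mean(ps), 0.4)
})

test_that("MGF files round-trip", {
  fix <- trunc_fixture()
  sp1 <- make_spectrum(fix$trunc, n_noise = 3, seed = 6)
  sp2 <- make_spectrum(fix$full, adduct = "[M-H]-", seed = 7)
  path <- tempfile(fileext = ".mgf")
  write_mgf(list(sp1, sp2), path)
  back <- read_mgf(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$spectrum_id, sp1$spectrum_id)
  expect_equal(back[[1]]$peaks$mz, sp1$peaks$mz, tolerance = 1e-6)
  expect_equal(back[[2]]$charge, -1L)
  expect_equal(back[[2]]$precursor_mz, sp2$precursor_mz, tolerance = 1e-6)
})

test_that("search ranks a planted candidate first among decoy candidates", {
  kb <- pkg_kb()
  fix <- trunc_fixture()
  # decoy candidates: other assembled structures from the catalog
  decoys <- unique(rbind(
    suppressWarnings(assemble_backbones(c("p03", "p06"), kb,
                                        max_backbones = 30))["smiles"],
    suppressWarnings(assemble_backbones(c("s04", "p03"), kb,
                                        max_backbones = 30))["smiles"],
    suppressWarnings(assemble_backbones(c("s06", "p06"), kb,
                                        max_backbones = 30))["smiles"],
    suppressWarnings(assemble_backbones(c("s02", "p05"), kb,
                                        max_backbones = 30))["smiles"],
    suppressWarnings(assemble_backbones(c("s13", "p06"), kb,
                                        max_backbones = 30))["smiles"]))
  cand <- data.frame(
    candidate_id = c("planted", sprintf("decoy%02d", seq_len(nrow(decoys)))),
    smiles = c(fix$trunc, decoys$smiles),
    stringsAsFactors = FALSE)
  cand$monoisotopic_mass <- vapply(cand$smiles, monoisotopic_mass, 0)
  expect_gte(nrow(cand), 50)
  sp <- make_spectrum(fix$trunc, seed = 9)
  res <- search_spectra(cand, list(sp), adducts = "[M+H]+",
                        n_decoys = 999, seed = 2)
  expect_equal(res$candidate_id[1], "planted")
  expect_lte(res$p_value[1], 1e-3)
  # empty spectra file
  empty <- tempfile(fileext = ".mgf"); writeLines(character(), empty)
  expect_equal(nrow(search_spectra(cand, empty)), 0)
  # precursor outside all candidate windows: no comparisons at all
  sp_far <- sp; sp_far$precursor_mz <- 5000
  expect_equal(nrow(search_spectra(cand, list(sp_far), adducts = "[M+H]+")),
               0)
})
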