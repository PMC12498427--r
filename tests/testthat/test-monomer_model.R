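# Fisher baseline and probabilistic monomer-set model.

test_that("fisher_pvalue matches its closed-form boundary cases", {
  expect_equal(fisher_pvalue(G = 50, N = 10, M = 0, O = 0), 1)
  expect_equal(fisher_pvalue(G = 50, N = 50, M = 5, O = 5), 1)
  expect_error(fisher_pvalue(G = 10, N = 4, M = 5, O = 6), "invalid")
})

test_that("fisher_pvalue equals brute-force enumeration over annotations", {
  # enumerate all C(10,4) annotated subsets; count those with overlap >= 3
  G <- 10; N <- 4; M <- 5; O <- 3
  required <- 1:M
  subsets <- utils::combn(G, N, simplify = FALSE)
  p_oracle <- mean(vapply(subsets, function(s)
    sum(s %in% required) >= O, TRUE))
  expect_equal(fisher_pvalue(G, N, M, O), p_oracle, tolerance = 1e-12)
})

test_that("fisher_pvalue agrees with the hypergeometric tail on a grid", {
  for (G in c(5, 8, 12)) for (N in 0:G) for (M in 0:G)
    for (O in 0:min(M, N)) {
      ours <- fisher_pvalue(G, N, M, O)
      ref <- stats::phyper(O - 1, M, G - M, N, lower.tail = FALSE)
      expect_equal(ours, ref, tolerance = 1e-12,
                   info = sprintf("G=%d N=%d M=%d O=%d", G, N, M, O))
    }
})

test_that("fisher_pvalue is non-increasing in the overlap", {
  for (O in 1:5)
    expect_lte(fisher_pvalue(50, 10, 8, O), fisher_pvalue(50, 10, 8, O - 1))
})

test_that("MLE returns the exact closed-form ratios on handbuilt counts", {
  # one pair engineered to give a=3, b=1, c=1, d=3, e=2, f=2
  pair <- list(g = c(1, 1, 1, 0, 1, 0, 0, 0),
               b = c(1, 1, 1, 1, 0, 0, 0, 0),
               m = c(1, 1, 0, 0))
  fit <- fit_monomer_model(list(pair))
  expect_equal(unname(coef(fit)), c(0.75, 0.25, 0.5))
  expect_equal(unname(fit$counts), c(3, 1, 1, 3, 2, 2))
  expect_equal(fit$counts[["a"]] + fit$counts[["b"]] + fit$counts[["c"]] +
                 fit$counts[["d"]], fit$n_pairs * fit$G)
})

test_that("degenerate training data is flagged", {
  # all genes present and required: beta denominator is zero
  all1 <- list(g = rep(1, 4), b = rep(1, 4), m = c(1, 0))
  expect_error(fit_monomer_model(list(all1)), "beta denominator")
  # boundary estimate triggers a warning
  pair <- list(g = c(1, 1, 0, 0), b = c(1, 1, 0, 0), m = c(1, 0))
  expect_warning(fit_monomer_model(list(pair)), "degenerate")
})

test_that("parameters are recovered from simulated pairs within 0.05", {
  truth <- c(alpha = 0.9, beta = 0.05, gamma = 0.3)
  pairs <- make_training_pairs(500, G = 50, K = 6, alpha = truth["alpha"],
                               beta = truth["beta"], gamma = truth["gamma"],
                               seed = 101)
  est <- coef(fit_monomer_model(pairs))
  expect_true(all(abs(est - truth) < 0.05))
  # bias shrinks with sample size (checked at two sizes, fixed seeds)
  est50 <- coef(fit_monomer_model(make_training_pairs(
    50, alpha = 0.9, beta = 0.05, gamma = 0.3, seed = 102)))
  expect_true(all(abs(est50 - truth) < 0.15))
})

test_that("log_probability matches its closed forms", {
  params <- c(alpha = 0.8, beta = 0.1, gamma = 0.25)
  G <- 6; K <- 3
  zero <- rep(0, G)
  # all-zero labels against an all-zero BGC
  expect_equal(log_probability(zero, rep(0, K), zero, params),
               G * log(1 - 0.1) + K * log(1 - 0.25))
  # flipping one g_i where b_i = 1 changes the value by log(alpha/(1-alpha))
  b <- c(1, rep(0, G - 1))
  g0 <- zero; g1 <- c(1, rep(0, G - 1))
  m <- rep(0, K)
  expect_equal(log_probability(g1, m, b, params) -
                 log_probability(g0, m, b, params),
               log(0.8 / (1 - 0.8)))
  expect_error(log_probability(c(0, 1), m, b, params), "dimensions")
})

test_that("probabilities normalize over the whole saccharide-vector space", {
  # brute force over all 2^(G+K) label vectors for G = 3, K = 2
  params <- c(alpha = 0.7, beta = 0.15, gamma = 0.4)
  G <- 3; K <- 2
  for (bpat in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    tot <- 0
    for (i in 0:(2^(G + K) - 1)) {
      bits <- as.integer(intToBits(i))[1:(G + K)]
      tot <- tot + exp(log_probability(bits[1:G], bits[(G + 1):(G + K)],
                                       bpat, params))
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("model methods expose the classic fitting interface", {
  pairs <- make_training_pairs(40, seed = 5)
  fit <- fit_monomer_model(pairs)
  expect_s3_class(fit, "monomer_model")
  expect_named(coef(fit), c("alpha", "beta", "gamma"))
  expect_output(print(fit), "alpha")
  expect_output(summary(fit), "log-likelihood")
  expect_s3_class(logLik(fit), "logLik")
  # simulate() re-draws from the fitted parameters at the same dimensions
  sim <- simulate(fit, nsim = 10, seed = 2)
  expect_length(sim, 10)
  expect_length(sim[[1]]$g, fit$G)
  # predict() scores a saccharide/BGC pair
  sv <- list(g = sim[[1]]$g, m = sim[[1]]$m)
  expect_equal(predict(fit, sv, sim[[1]]$b),
               log_probability(sv$g, sv$m, sim[[1]]$b, coef(fit)))
})

test_that("ranked-set enumeration matches the brute-force multiset count", {
  kb <- toy_kb()
  b <- setNames(integer(8), kb$gene_classes$id)
  b[c("ga01", "ga02", "ga03")] <- 1L   # all 3 secondary eligible
  params <- c(alpha = 0.9, beta = 0.05, gamma = 0.3)
  rs <- enumerate_ranked_sets(b, kb, params, max_monomers = 3,
                              max_primary = 2, max_multiplicity = 1,
                              top_n = Inf)
  # oracle: count multisets of {5 monomers}, size 1..3, multiplicity <= 1,
  # <= 2 primary, by explicit expansion
  grid <- expand.grid(rep(list(0:1), 5))
  names(grid) <- c("tA", "tB", "tC", "tP1", "tP2")
  sz <- rowSums(grid)
  np <- grid$tP1 + grid$tP2
  expect_equal(nrow(rs), sum(sz >= 1 & sz <= 3 & np <= 2))
})

test_that("eligibility and ranking follow gene support", {
  kb <- toy_kb()
  zero <- setNames(integer(8), kb$gene_classes$id)
  params <- c(alpha = 0.9, beta = 0.05, gamma = 0.3)
  # zero presence vector, relaxation off: only all-primary sets
  expect_warning(
    rs0 <- enumerate_ranked_sets(zero, kb, params, max_monomers = 2,
                                 top_n = Inf),
    "no secondary monomer")
  expect_true(all(rs0$n_primary == rs0$n_monomers))
  # relaxation admits gene-free secondary monomers through the beta penalty
  rs1 <- enumerate_ranked_sets(zero, kb, params, max_monomers = 2,
                               top_n = Inf, relax = TRUE)
  expect_true(any(rs1$n_primary < rs1$n_monomers))
  # a gene-supported set outranks an equal-size unsupported one (alpha >
  # beta)
  b <- zero; b["ga01"] <- 1L
  rs <- enumerate_ranked_sets(b, kb, params, max_monomers = 1,
                              top_n = Inf, relax = TRUE)
  expect_lt(rs$rank[rs$monomers == "tA x 1"],
            rs$rank[rs$monomers == "tB x 1"])
})

test_that("rankings are deterministic with lexicographic tie-breaks", {
  kb <- toy_kb()
  b <- setNames(integer(8), kb$gene_classes$id)
  b[c("ga01", "ga02")] <- 1L
  params <- c(alpha = 0.9, beta = 0.05, gamma = 0.3)
  r1 <- enumerate_ranked_sets(b, kb, params, max_monomers = 3, top_n = 100)
  r2 <- enumerate_ranked_sets(b, kb, params, max_monomers = 3, top_n = 100)
  expect_identical(r1, r2)
  # ties (same score) are ordered by monomer-id signature
  ties <- r1[duplicated(r1$log_probability) |
               duplicated(r1$log_probability, fromLast = TRUE), ]
  if (nrow(ties) > 1)
    for (sc in unique(ties$log_probability)) {
      keys <- ties$monomers[ties$log_probability == sc]
      expect_identical(keys, sort(keys))
    }
})

test_that("baseline ranking orders sets by Fisher p-value", {
  kb <- toy_kb()
  b <- setNames(integer(8), kb$gene_classes$id)
  b[c("ga01")] <- 1L
  rs <- enumerate_ranked_sets(b, kb, model = "baseline", max_monomers = 2,
                              top_n = Inf)
  expect_true(all(diff(rs$p_value) >= 0))
  expect_true("p_value" %in% names(rs))
  # the supported monomer tops the list
  expect_equal(glycomine:::parse_set_key(rs$monomers[1]), "tA")
})
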