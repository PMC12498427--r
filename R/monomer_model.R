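# Monomer-set selection.
#
# Two rankings of candidate monomer multisets for a BGC are provided. The
# baseline scores a set by the upper-tail Fisher's exact (hypergeometric)
# probability of the overlap between the gene classes the set requires and
# those annotated in the BGC. The probabilistic model scores the full
# gene-presence pattern: each gene class i contributes P(g_i | b_i) with
#   P(g=1|b=1) = alpha     P(g=1|b=0) = beta
#   P(g=0|b=1) = 1-alpha   P(g=0|b=0) = 1-beta
# and each primary monomer j contributes P(m_j) = gamma^m (1-gamma)^(1-m).
# alpha is the chance a gene found in the BGC is actually used by the
# product; beta the chance a required gene was missed by annotation. The
# closed-form maximum-likelihood estimates from labelled (saccharide, BGC)
# pairs are alpha = a/(a+b), beta = c/(c+d), gamma = e/(e+f) where a..f
# aggregate the four (g,b) label combinations and the primary-monomer
# presence counts over all training pairs.

#' Upper-tail Fisher's exact probability of gene-set overlap
#'
#' For G gene classes total, N annotated in the BGC, M required by a
#' candidate monomer set and an observed overlap of O, returns
#' \deqn{P = \sum_{i \ge O} \binom{M}{i}\binom{G-M}{N-i} / \binom{G}{N}}
#' the probability of an overlap at least as large under random annotation.
#'
#' @param G,N,M,O contingency counts (see Details).
#' @return probability in [0, 1].
#' @export
#' @examples
#' fisher_pvalue(G = 50, N = 10, M = 0, O = 0)  # 1
fisher_pvalue <- function(G, N, M, O) {
  stopifnot(length(G) == 1, length(N) == 1, length(M) == 1, length(O) == 1)
  if (any(c(G, N, M, O) < 0) || M > G || N > G || O > min(M, N))
    stop("invalid contingency counts")
  i <- seq.int(O, min(M, N))
  # stable exact sum of hypergeometric terms on the log scale
  lt <- lchoose(M, i) + lchoose(G - M, N - i) - lchoose(G, N)
  p <- sum(exp(lt))
  min(1, max(0, p))
}

#' Fit the probabilistic monomer-set model
#'
#' Computes the closed-form maximum-likelihood estimates of (alpha, beta,
#' gamma) from training pairs of saccharide label vectors and BGC presence
#' vectors.
#'
#' @param pairs a list of training pairs; each pair is a list with binary
#'   vectors `g` (length G, gene class required by the molecule), `m`
#'   (length K, primary monomer present) and `b` (length G, gene class
#'   annotated in the BGC). See [make_training_pairs()].
#' @return an object of class `monomer_model` with the parameter estimates,
#'   the aggregated training counts and the training dimensions.
#' @seealso [log_probability()], [enumerate_ranked_sets()]
#' @export
fit_monomer_model <- function(pairs) {
  if (!length(pairs)) stop("at least one training pair is required")
  G <- length(pairs[[1]]$g); K <- length(pairs[[1]]$m)
  for (p in pairs)
    if (length(p$g) != G || length(p$b) != G || length(p$m) != K)
      stop("training pairs have inconsistent dimensions")
  a <- b <- cc <- d <- e <- f <- 0L
  for (p in pairs) {
    g <- as.integer(p$g); bb <- as.integer(p$b); m <- as.integer(p$m)
    a <- a + sum(g == 1 & bb == 1)
    b <- b + sum(g == 0 & bb == 1)
    cc <- cc + sum(g == 1 & bb == 0)
    d <- d + sum(g == 0 & bb == 0)
    e <- e + sum(m == 1)
    f <- f + sum(m == 0)
  }
  stopifnot(a + b + cc + d == length(pairs) * G,
            e + f == length(pairs) * K)
  if (a + b == 0) stop("no gene class present in any training BGC: ",
                       "alpha denominator is zero")
  if (cc + d == 0) stop("every gene class present in every training BGC: ",
                        "beta denominator is zero")
  if (e + f == 0) stop("gamma denominator is zero")
  est <- c(alpha = a / (a + b), beta = cc / (cc + d), gamma = e / (e + f))
  if (any(est %in% c(0, 1)))
    warning("degenerate parameter estimate at the boundary: ",
            paste(names(est)[est %in% c(0, 1)], collapse = ", "))
  structure(list(
    params = est,
    counts = c(a = a, b = b, c = cc, d = d, e = e, f = f),
    n_pairs = length(pairs), G = G, K = K,
    call = match.call()
  ), class = "monomer_model")
}

#' @export
print.monomer_model <- function(x, ...) {
  cat("Probabilistic monomer-set model\n")
  cat(sprintf("  trained on %d (saccharide, BGC) pairs (G = %d, K = %d)\n",
              x$n_pairs, x$G, x$K))
  cat(sprintf("  alpha = %.4f  beta = %.4f  gamma = %.4f\n",
              x$params["alpha"], x$params["beta"], x$params["gamma"]))
  invisible(x)
}

#' @export
coef.monomer_model <- function(object, ...) object$params

#' @export
summary.monomer_model <- function(object, ...) {
  cnt <- object$counts
  cat("Probabilistic monomer-set model\n\n")
  cat("Aggregated training counts:\n")
  print(cnt)
  cat(sprintf("\nalpha = a/(a+b) = %d/%d = %.4f  (P(gene required | present))\n",
              cnt["a"], cnt["a"] + cnt["b"], object$params["alpha"]))
  cat(sprintf("beta  = c/(c+d) = %d/%d = %.4f  (P(gene required | absent))\n",
              cnt["c"], cnt["c"] + cnt["d"], object$params["beta"]))
  cat(sprintf("gamma = e/(e+f) = %d/%d = %.4f  (P(primary monomer present))\n",
              cnt["e"], cnt["e"] + cnt["f"], object$params["gamma"]))
  cat(sprintf("\nlog-likelihood: %.3f on %d pairs\n",
              as.numeric(logLik(object)), object$n_pairs))
  invisible(object)
}

#' @export
logLik.monomer_model <- function(object, ...) {
  p <- object$params; cnt <- object$counts
  xlog <- function(n, q) if (n == 0) 0 else n * log(q)
  ll <- xlog(cnt["a"], p["alpha"]) + xlog(cnt["b"], 1 - p["alpha"]) +
        xlog(cnt["c"], p["beta"]) + xlog(cnt["d"], 1 - p["beta"]) +
        xlog(cnt["e"], p["gamma"]) + xlog(cnt["f"], 1 - p["gamma"])
  structure(as.numeric(ll), df = 3, nobs = object$n_pairs, class = "logLik")
}

#' @export
predict.monomer_model <- function(object, saccharide, bgc, ...) {
  log_probability(saccharide$g, saccharide$m, bgc, object$params)
}

#' @export
simulate.monomer_model <- function(object, nsim = 1, seed = NULL, ...) {
  make_training_pairs(n_pairs = nsim, G = object$G, K = object$K,
                      alpha = object$params["alpha"],
                      beta = object$params["beta"],
                      gamma = object$params["gamma"], seed = seed)
}

#' Log-probability of a saccharide label vector given a BGC
#'
#' @param g binary vector (length G): gene class required by the molecule.
#' @param m binary vector (length K): primary monomer present.
#' @param b binary vector (length G): gene class annotated in the BGC.
#' @param params named vector with `alpha`, `beta`, `gamma`, or a fitted
#'   `monomer_model`.
#' @return the log-probability; `-Inf` when a zero-probability case occurs.
#' @export
log_probability <- function(g, m, b, params) {
  if (inherits(params, "monomer_model")) params <- params$params
  if (length(g) != length(b)) stop("g and b dimensions differ")
  al <- params[["alpha"]]; be <- params[["beta"]]; ga <- params[["gamma"]]
  g <- as.integer(g); b <- as.integer(b); m <- as.integer(m)
  pr_g <- ifelse(b == 1, ifelse(g == 1, al, 1 - al),
                         ifelse(g == 1, be, 1 - be))
  pr_m <- ifelse(m == 1, ga, 1 - ga)
  if (any(pr_g == 0) || any(pr_m == 0)) return(-Inf)
  sum(log(pr_g)) + sum(log(pr_m))
}

#' Saccharide label vector of a monomer multiset
#'
#' Maps a multiset of monomer ids to the (g, m) binary representation: g is
#' the union of the gene classes required by its secondary members (a gene
#' shared by two monomers counts once), m flags which primary monomers are
#' present.
#'
#' @param kb a `glyco_kb`.
#' @param monomer_ids character vector of monomer ids (repeats allowed).
#' @return list with named binary vectors `g` (gene classes) and `m`
#'   (primary monomers).
#' @export
saccharide_vector <- function(kb, monomer_ids) {
  mono <- kb$monomers
  unknown <- setdiff(monomer_ids, mono$id)
  if (length(unknown)) stop("unknown monomer id(s): ",
                            paste(unknown, collapse = ", "))
  idx <- match(unique(monomer_ids), mono$id)
  req <- unique(unlist(mono$required_gene_classes[idx]))
  g <- setNames(as.integer(kb$gene_classes$id %in% req), kb$gene_classes$id)
  prim <- mono$id[mono$is_primary]
  m <- setNames(as.integer(prim %in% monomer_ids), prim)
  list(g = g, m = m)
}

# all multisets over `alphabet` with the given caps; returns list of
# named integer count vectors
enumerate_multisets <- function(alphabet, max_size, max_multiplicity,
                                is_primary, max_primary) {
  alphabet <- sort(alphabet)
  out <- list()
  recurse <- function(i, counts, size, n_prim) {
    if (size > 0) out[[length(out) + 1L]] <<- counts[counts > 0]
    if (i > length(alphabet) || size == max_size) return()
    for (k in i:length(alphabet)) {
      prim_k <- is_primary[[alphabet[k]]]
      max_here <- min(max_multiplicity, max_size - size,
                      if (prim_k) max_primary - n_prim else Inf)
      if (max_here < 1) next
      for (mult in 1:max_here) {
        counts2 <- counts
        counts2[alphabet[k]] <- mult
        recurse(k + 1L, counts2, size + mult,
                n_prim + if (prim_k) mult else 0L)
      }
    }
  }
  recurse(1L, setNames(integer(length(alphabet)), alphabet), 0L, 0L)
  out
}

#' Enumerate and rank candidate monomer multisets for a BGC
#'
#' Enumerates all monomer multisets within the limits and ranks them. A
#' secondary monomer is eligible when at least one of its required gene
#' classes is present in the BGC; `relax = TRUE` admits every secondary
#' monomer, with unsupported required genes paying the beta penalty.
#' Primary monomers are always eligible, up to `max_primary` instances per
#' set. With `model = "probabilistic"` sets are sorted by decreasing
#' log-probability; with `model = "baseline"` by increasing Fisher's exact
#' p-value over the biosynthesis gene classes. Ties are broken by the
#' lexicographic monomer-id signature, so rankings are deterministic.
#'
#' @param bgc binary presence vector named by gene-class id (see
#'   [presence_vector()]).
#' @param kb a `glyco_kb`.
#' @param params fitted `monomer_model` or named (alpha, beta, gamma)
#'   vector; ignored for the baseline model.
#' @param model `"probabilistic"` (default) or `"baseline"`.
#' @param max_monomers largest multiset size (default 7).
#' @param max_primary maximum primary-monomer instances per set (default 2).
#' @param max_multiplicity per-monomer copy cap (default 3).
#' @param top_n number of ranked sets returned (default 500).
#' @param relax admit secondary monomers with no detected gene (default
#'   FALSE).
#' @return data.frame with columns `rank`, `monomers` (comma-joined
#'   "id x mult"), `n_monomers`, `n_primary`, `log_probability` (or
#'   `p_value` for the baseline), ordered by rank.
#' @export
enumerate_ranked_sets <- function(bgc, kb, params = NULL,
                                  model = c("probabilistic", "baseline"),
                                  max_monomers = 7, max_primary = 2,
                                  max_multiplicity = 3, top_n = 500,
                                  relax = FALSE) {
  model <- match.arg(model)
  mono <- kb$monomers
  present <- names(bgc)[bgc > 0]
  eligible_sec <- mono$id[!mono$is_primary &
    vapply(mono$required_gene_classes, function(cl)
      relax || any(cl %in% present), TRUE)]
  alphabet <- c(mono$id[mono$is_primary], eligible_sec)
  if (!length(eligible_sec) && !relax)
    warning("no secondary monomer has gene support in this BGC; ",
            "only all-primary sets will be enumerated")
  is_primary <- setNames(as.list(mono$is_primary), mono$id)
  sets <- enumerate_multisets(alphabet, max_monomers, max_multiplicity,
                              is_primary, max_primary)
  if (!length(sets))
    return(data.frame(rank = integer(), monomers = character(),
                      n_monomers = integer(), n_primary = integer(),
                      score = numeric()))
  key <- vapply(sets, function(s)
    paste(sprintf("%s x %d", names(s), s), collapse = ","), "")
  n_mono <- vapply(sets, sum, 0L)
  n_prim <- vapply(sets, function(s)
    sum(s[vapply(names(s), function(id) is_primary[[id]], TRUE)]), 0L)
  if (model == "probabilistic") {
    if (inherits(params, "monomer_model")) params <- params$params
    if (is.null(params)) stop("probabilistic ranking requires parameters")
    params <- c(alpha = unname(params[["alpha"]]),
                beta = unname(params[["beta"]]),
                gamma = unname(params[["gamma"]]))
    score <- vapply(sets, function(s) {
      sv <- saccharide_vector(kb, rep(names(s), s))
      log_probability(sv$g, sv$m, bgc, params)
    }, 0)
    ord <- order(-score, key)
    res <- data.frame(monomers = key, n_monomers = n_mono,
                      n_primary = n_prim, log_probability = score)[ord, ]
  } else {
    bio <- kb_biosynthesis_classes(kb)
    Gb <- length(bio)
    Nb <- sum(present %in% bio)
    score <- vapply(sets, function(s) {
      req <- unique(unlist(mono$required_gene_classes[
        match(unique(names(s)), mono$id)]))
      M <- length(req)
      O <- sum(req %in% present)
      fisher_pvalue(Gb, Nb, M, O)
    }, 0)
    ord <- order(score, key)
    res <- data.frame(monomers = key, n_monomers = n_mono,
                      n_primary = n_prim, p_value = score)[ord, ]
  }
  res <- utils::head(res, top_n)
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
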