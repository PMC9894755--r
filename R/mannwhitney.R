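# Vectorised Mann-Whitney U machinery.
#
# The enrichment permutation null recomputes a full per-feature scan under
# thousands of label permutations, so the scan is expressed as matrix
# products: per-feature midranks (0 at missing cells) against a samples x
# permutations case-indicator matrix. The same code path produces the
# observed scan, so observed and null statistics can never diverge by an
# approximation switch.

mw_prep <- function(values) {
  obs <- !is.na(values)
  rank0 <- values
  tie_term <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) {
    o <- obs[, j]
    r <- rank(values[o, j], ties.method = "average")
    rank0[o, j] <- r
    rank0[!o, j] <- 0
    tt <- table(values[o, j])
    tie_term[j] <- sum(tt^3 - tt)
  }
  list(rank0 = rank0, obs = obs * 1, tie_term = tie_term,
       n_obs = colSums(obs))
}

# U statistics and two-sided p-values for every feature under every column
# of `cases` (samples x n_label_vectors, 0/1). Tie-corrected normal
# approximation with continuity correction; features x columns matrices out.
mw_scan <- function(prep, cases) {
  cases <- as.matrix(cases)
  n1 <- crossprod(prep$obs, cases)              # features x cols
  n <- prep$n_obs
  n2 <- n - n1
  r1 <- crossprod(prep$rank0, cases)
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig2 <- (n1 * n2 / 12) * ((n + 1) - prep$tie_term / pmax(n * (n - 1), 1))
  d <- u - mu
  z <- (d - sign(d) * 0.5) / sqrt(pmax(sig2, .Machine$double.eps))
  p <- 2 * pnorm(-abs(z))
  p[sig2 <= 0] <- 1
  p <- pmin(p, 1)
  list(U = u, p = p, n1 = n1, n2 = n2)
}

# Exact two-sided p for a single feature without ties (wilcox.test
# convention), used by association_scan when n1 * n2 is small.
mw_exact_p <- function(u, n1, n2) {
  if (u > n1 * n2 / 2) {
    p <- 2 * (1 - pwilcox(u - 1, n1, n2))
  } else {
    p <- 2 * pwilcox(u, n1, n2)
  }
  min(1, p)
}
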