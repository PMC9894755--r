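#' Estimate absolute taxon abundances from relative abundances and qPCR load
#'
#' Multiplies each sample's relative abundances by its total 16S copy
#' number. Samples lacking a load value are excluded (no load imputation is
#' ever performed in the correlation-network context) and recorded.
#'
#' @param taxa a [taxa_table()].
#' @return A samples x taxa matrix of absolute abundances, with attribute
#'   `excluded_samples` listing the samples dropped for missing load.
#' @export
estimate_absolute_abundance <- function(taxa) {
  stopifnot(inherits(taxa, "taxa_table"))
  load <- taxa$total_load
  if (any(load <= 0, na.rm = TRUE)) abort_vagmet("total load must be positive")
  keep <- !is.na(load)
  abs_mat <- sweep(taxa$rel_abundance[keep, , drop = FALSE], 1L, load[keep], "*")
  attr(abs_mat, "excluded_samples") <- rownames(taxa$rel_abundance)[!keep]
  abs_mat
}

# Spearman rho and p for one pair of complete vectors; exact enumeration
# below `exact_below` pairs, t-approximation with midrank ties otherwise.
spearman_pair <- function(x, y, exact_below = 10L) {
  n <- length(x)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n < exact_below)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Microbe-metabolite Spearman correlation network
#'
#' Spearman correlations between absolute taxon abundances and raw
#' metabolite levels, on pairwise-complete observations only: a missing
#' metabolite value drops the pair, while a taxon zero is data (observed
#' absence). No imputation ever occurs here. Edges are kept when they pass
#' the Benjamini-Hochberg threshold across all computed edges and the
#' correlation-magnitude threshold; pairs with too few complete
#' observations or a constant vector are recorded with reasons, not
#' computed.
#'
#' @param abs_taxa samples x taxa absolute-abundance matrix (from
#'   [estimate_absolute_abundance()]).
#' @param mat a raw-scale [metab_matrix()], typically restricted to the
#'   outcome-associated metabolites of interest.
#' @param min_pair_fraction minimum complete-pair fraction of the cohort;
#'   the threshold in samples is `ceiling(min_pair_fraction * n_cohort)`.
#' @param min_pairs explicit integer override of the pairing threshold
#'   (takes precedence over `min_pair_fraction` when given).
#' @param q_max,rho_min edge-keeping thresholds (`q < q_max`,
#'   `|rho| > rho_min`).
#' @param n_cohort cohort size used for the fraction arithmetic; defaults
#'   to the number of samples shared by the two tables.
#' @return A tibble of network edges (`taxon_id`, `feature_id`, `rho`,
#'   `n_pairs`, `p`, `q`, `kept`), with attribute `uncomputed` (pairs
#'   skipped, with reasons) and `threshold` (the pairing threshold used).
#' @export
correlation_network <- function(abs_taxa, mat, min_pair_fraction = 0.22,
                                min_pairs = NULL, q_max = 0.1, rho_min = 0.25,
                                n_cohort = NULL) {
  stopifnot(inherits(mat, "metab_matrix"))
  shared <- intersect(rownames(abs_taxa), sample_ids(mat))
  if (length(shared) == 0L) abort_vagmet("no shared samples between taxa and metabolites")
  n_cohort <- n_cohort %||% length(shared)
  threshold <- if (!is.null(min_pairs)) as.integer(min_pairs) else
    as.integer(ceiling(min_pair_fraction * n_cohort))
  tx <- abs_taxa[shared, , drop = FALSE]
  mv <- mat$values[shared, , drop = FALSE]
  edges <- list()
  skipped <- list()
  for (t in colnames(tx)) {
    xt <- tx[, t]
    for (f in colnames(mv)) {
      yf <- mv[, f]
      ok <- !is.na(yf) # taxon zeros are observed; only metabolite NAs drop pairs
      n_pairs <- sum(ok)
      if (n_pairs < threshold) {
        skipped[[length(skipped) + 1L]] <- tibble(
          taxon_id = t, feature_id = f, n_pairs = n_pairs,
          reason = sprintf("fewer than %d complete pairs", threshold)
        )
        next
      }
      x <- xt[ok]
      y <- yf[ok]
      if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
        skipped[[length(skipped) + 1L]] <- tibble(
          taxon_id = t, feature_id = f, n_pairs = n_pairs,
          reason = "constant vector"
        )
        next
      }
      sp <- spearman_pair(x, y)
      edges[[length(edges) + 1L]] <- tibble(
        taxon_id = t, feature_id = f, rho = sp$rho,
        n_pairs = n_pairs, p = sp$p
      )
    }
  }
  out <- bind_rows(edges)
  if (nrow(out) > 0L) {
    out$q <- bh_fdr(out$p)
    out$kept <- out$q < q_max & abs(out$rho) > rho_min & out$n_pairs >= threshold
  }
  attr(out, "uncomputed") <- bind_rows(skipped)
  attr(out, "threshold") <- threshold
  out
}

#' Compare a correlation between two subgroups (Fisher r-to-z)
#'
#' `z = (atanh(rho_a) - atanh(rho_b)) / sqrt(var_a + var_b)` with the
#' classical `1 / (n - 3)` variances (the `1.06 / (n - 3)` rank-correlation
#' variant is available via `spearman_variance`), two-sided normal p.
#'
#' @param x,y numeric vectors (e.g. absolute taxon abundance and metabolite
#'   level); pairs with a missing value in either are dropped per subgroup.
#' @param group two-level factor over the samples.
#' @param spearman_variance use `1.06 / (n - 3)` instead of `1 / (n - 3)`.
#' @return A tibble row: the two groups' `rho` and `n`, `z`, `p`.
#' @export
compare_correlation_subgroups <- function(x, y, group, spearman_variance = FALSE) {
  lev <- if (is.factor(group)) {
    intersect(levels(group), as.character(group[!is.na(group)]))
  } else {
    unique(as.character(group[!is.na(group)]))
  }
  if (length(lev) != 2L) abort_vagmet("exactly two subgroups required")
  one <- function(g) {
    i <- which(group == g & !is.na(x) & !is.na(y))
    if (length(i) < 4L) abort_vagmet(sprintf("subgroup '%s' has fewer than 4 complete pairs", g))
    list(rho = cor(x[i], y[i], method = "spearman"), n = length(i))
  }
  a <- one(lev[1L])
  b <- one(lev[2L])
  if (abs(a$rho) >= 1 - 1e-12 || abs(b$rho) >= 1 - 1e-12) {
    abort_vagmet("|rho| = 1: Fisher transform is infinite; comparison undefined")
  }
  k <- if (spearman_variance) 1.06 else 1
  z <- (atanh(a$rho) - atanh(b$rho)) /
    sqrt(k / (a$n - 3) + k / (b$n - 3))
  tibble(
    group_a = lev[1L], group_b = lev[2L],
    rho_a = a$rho, n_a = a$n, rho_b = b$rho, n_b = b$n,
    z = z, p = 2 * pnorm(-abs(z))
  )
}

#' Contrast edge strengths between two feature groups
#'
#' Two-sided Mann-Whitney test on the absolute correlation magnitudes of
#' all computed edges touching group-1 features versus group-2 features
#' (e.g. xenobiotic-like metabolites versus the rest).
#'
#' @param edges edge tibble from [correlation_network()].
#' @param group1,group2 character vectors of feature ids.
#' @return A list: `U`, `p`, `n1`, `n2`, `median_abs_rho_1`,
#'   `median_abs_rho_2`.
#' @export
compare_edge_strength_groups <- function(edges, group1, group2) {
  r1 <- abs(edges$rho[edges$feature_id %in% group1])
  r2 <- abs(edges$rho[edges$feature_id %in% group2])
  if (length(r1) == 0L || length(r2) == 0L) {
    abort_vagmet("both feature groups need at least one computed edge")
  }
  wt <- wilcox.test(r1, r2, alternative = "two.sided", exact = FALSE, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(r1), n2 = length(r2),
       median_abs_rho_1 = median(r1), median_abs_rho_2 = median(r2))
}
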