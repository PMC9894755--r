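#' Pairwise sample distances
#'
#' Canberra (for standardized metabolome vectors; coordinate terms
#' `|x - y| / (|x| + |y|)`, a `0/0` coordinate contributing 0) or
#' Bray-Curtis (for non-negative microbiome abundances, via
#' [vegan::vegdist()]).
#'
#' @param x a complete [metab_matrix()] or plain numeric matrix (samples in
#'   rows).
#' @param metric `"canberra"` or `"bray_curtis"`.
#' @return A `vm_dist` object: the symmetric distance matrix plus a metric
#'   tag.
#' @export
compute_distance <- function(x, metric = c("canberra", "bray_curtis")) {
  metric <- match.arg(metric)
  v <- if (inherits(x, "metab_matrix")) x$values else x
  if (anyNA(v)) abort_vagmet("distance computation needs a complete matrix (impute first)")
  if (metric == "bray_curtis") {
    if (any(v < 0)) abort_vagmet("Bray-Curtis requires non-negative input")
    D <- as.matrix(vegan::vegdist(v, method = "bray"))
  } else {
    D <- canberra_pairwise(v)
    dimnames(D) <- list(rownames(v), rownames(v))
  }
  structure(list(D = D, sample_ids = rownames(v), metric_tag = metric),
            class = "vm_dist")
}

#' @export
print.vm_dist <- function(x, ...) {
  cat(sprintf("<vm_dist> %d samples, metric = %s\n", nrow(x$D), x$metric_tag))
  invisible(x)
}

#' Wrap a precomputed square distance matrix
#'
#' @param D symmetric matrix with sample-id dimnames.
#' @param metric_tag metric label carried along.
#' @return A `vm_dist` object.
#' @export
as_vm_dist <- function(D, metric_tag = "canberra") {
  D <- as.matrix(D)
  structure(list(D = D, sample_ids = rownames(D), metric_tag = metric_tag),
            class = "vm_dist")
}

# Anderson's sum-of-squares decomposition of a squared distance matrix for
# one grouping: returns pseudo-F given group index list.
permanova_f <- function(D2, groups_idx, n, a) {
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (idx in groups_idx) {
    sub <- D2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way pseudo-F from the among/within decomposition of squared
#' distances, with a permutation p-value under random relabelling and the
#' `+1` floor (`p >= 1 / (n_permutations + 1)`; never exactly zero).
#'
#' @param d a `vm_dist` from [compute_distance()] (or a square matrix).
#' @param groups categorical labels, one per sample, in matrix order.
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @param permutations optional matrix of explicit label orderings (one row
#'   per permutation, columns indexing samples); when given, the p-value is
#'   the exact fraction of orderings with `F* >= F_obs` (exhaustive
#'   enumeration) and `n_permutations`/`seed` are ignored.
#' @return A list of class `permanova_result` with `pseudo_F`, `p`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L,
                      permutations = NULL) {
  D <- if (inherits(d, "vm_dist")) d$D else as.matrix(d)
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) abort_vagmet("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2L) abort_vagmet("PERMANOVA needs at least two groups")
  if (any(tab < 2L)) abort_vagmet("every group needs at least two members")
  a <- length(tab)
  D2 <- D^2
  split_idx <- function(g) split(seq_len(n), g)
  f_obs <- permanova_f(D2, split_idx(groups), n, a)
  if (!is.null(permutations)) {
    fs <- apply(permutations, 1L, function(o) {
      permanova_f(D2, split_idx(groups[o]), n, a)
    })
    return(structure(list(
      pseudo_F = f_obs, p = mean(fs >= f_obs - 1e-12),
      n_permutations = nrow(permutations), seed = NA_integer_
    ), class = "permanova_result"))
  }
  exceed <- 0L
  with_seed(substream_seed(seed, "permanova"), {
    for (b in seq_len(n_permutations)) {
      gp <- sample(groups)
      if (permanova_f(D2, split_idx(gp), n, a) >= f_obs) exceed <- exceed + 1L
    }
  })
  structure(list(
    pseudo_F = f_obs,
    p = (1 + exceed) / (1 + n_permutations),
    n_permutations = n_permutations,
    seed = seed
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p, x$n_permutations))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) of the upper-triangle entries, with a
#' permutation p-value obtained by jointly permuting rows and columns of the
#' second matrix; `+1` floor applies.
#'
#' @param d1,d2 `vm_dist` objects (or square matrices) over the same samples
#'   in the same order.
#' @param n_permutations,seed permutation settings.
#' @param method correlation type for the triangle entries.
#' @return A list with `r`, `p`, `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999L, seed = 1L,
                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  M1 <- if (inherits(d1, "vm_dist")) d1$D else as.matrix(d1)
  M2 <- if (inherits(d2, "vm_dist")) d2$D else as.matrix(d2)
  if (!identical(dim(M1), dim(M2))) abort_vagmet("distance matrices differ in size")
  if (!is.null(rownames(M1)) && !is.null(rownames(M2)) &&
      !identical(rownames(M1), rownames(M2))) {
    abort_vagmet("distance matrices must cover the same samples in the same order")
  }
  ut <- upper.tri(M1)
  r_obs <- cor(M1[ut], M2[ut], method = method)
  n <- nrow(M1)
  exceed <- 0L
  with_seed(substream_seed(seed, "mantel"), {
    for (b in seq_len(n_permutations)) {
      o <- sample.int(n)
      if (cor(M1[ut], M2[o, o][ut], method = method) >= r_obs) exceed <- exceed + 1L
    }
  })
  list(r = r_obs, p = (1 + exceed) / (1 + n_permutations),
       n_permutations = n_permutations, seed = seed)
}

#' k-medoids clustering on a precomputed distance matrix
#'
#' Partitioning around medoids (deterministic BUILD initialization followed
#' by SWAP, via [cluster::pam()]); given the same distance matrix and `k`
#' the result is identical on every run.
#'
#' @param d a `vm_dist` (or square matrix).
#' @param k number of clusters, `1 <= k <= n`.
#' @return A `clustering_result`: `k`, `medoid_ids`, `assignment` (named
#'   integer vector), and `W` (total within-cluster distance to medoids).
#' @export
kmedoids_fit <- function(d, k) {
  D <- if (inherits(d, "vm_dist")) d$D else as.matrix(d)
  n <- nrow(D)
  if (k < 1L || k > n) abort_vagmet("k must lie in [1, n_samples]")
  ids <- rownames(D) %||% as.character(seq_len(n))
  if (k == n) {
    assignment <- setNames(seq_len(n), ids)
    return(structure(list(k = k, medoid_ids = ids, assignment = assignment, W = 0),
                     class = "clustering_result"))
  }
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE, pamonce = 5,
                      keep.diss = FALSE)
  assignment <- setNames(as.integer(fit$clustering), ids)
  medoids <- ids[fit$id.med]
  w <- sum(D[cbind(seq_len(n), fit$id.med[fit$clustering])])
  structure(list(k = k, medoid_ids = medoids, assignment = assignment, W = w),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d, W = %.3f, sizes: %s\n",
              x$k, x$W, paste(table(x$assignment), collapse = "/")))
  invisible(x)
}

#' Gap-statistic selection of the cluster count
#'
#' Clusters the data at each `k` in `k_range` and compares `log W_k` with
#' its expectation under `B` reference datasets drawn uniformly over each
#' feature's observed range:
#' `Gap(k) = mean_b log W_k(ref_b) - log W_k(data)`. The headline `chosen_k`
#' is the smallest `k` with `Gap(k) >= Gap(k+1) - s_{k+1}` (the one-SE
#' rule); the argmax of the gap curve is reported alongside.
#'
#' @param x complete [metab_matrix()] or numeric matrix (samples x
#'   features) used to draw reference data.
#' @param metric distance metric passed to [compute_distance()].
#' @param k_range candidate cluster counts.
#' @param B number of reference datasets (`>= 10`).
#' @param seed integer seed for the reference draws.
#' @return A `gap_curve`: tibble `curve` (`k`, `W`, `log_W`, `E_log_W`,
#'   `gap`, `s`), `chosen_k`, `argmax_k`, `B`, `seed`, and the `fit` at
#'   `chosen_k`.
#' @export
select_k_gap <- function(x, metric = "canberra", k_range = 1:15, B = 50L, seed = 1L) {
  v <- if (inherits(x, "metab_matrix")) x$values else x
  if (anyNA(v)) abort_vagmet("gap selection needs a complete matrix")
  if (B < 10L) abort_vagmet("B must be at least 10")
  if (all(apply(v, 2L, function(col) length(unique(col)) == 1L))) {
    abort_vagmet("degenerate data: all points identical")
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(v)) abort_vagmet("k_range exceeds the number of samples")
  Wk <- function(mat) {
    D <- compute_distance(mat, metric)
    vapply(k_range, function(k) kmedoids_fit(D, k)$W, numeric(1L))
  }
  log_w_data <- log(pmax(Wk(v), .Machine$double.xmin))
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  log_w_ref <- matrix(NA_real_, nrow = B, ncol = length(k_range))
  with_seed(substream_seed(seed, "gap_reference"), {
    for (b in seq_len(B)) {
      ref <- matrix(runif(length(v), min = rep(lo, each = nrow(v)),
                          max = rep(hi, each = nrow(v))),
                    nrow = nrow(v), dimnames = dimnames(v))
      log_w_ref[b, ] <- log(pmax(Wk(ref), .Machine$double.xmin))
    }
  })
  e_log_w <- colMeans(log_w_ref)
  gap <- e_log_w - log_w_data
  s <- apply(log_w_ref, 2L, sd) * sqrt(1 + 1 / B)
  chosen <- max(k_range)
  for (i in seq_len(length(k_range) - 1L)) {
    if (gap[i] >= gap[i + 1L] - s[i + 1L]) {
      chosen <- k_range[i]
      break
    }
  }
  curve <- tibble(k = k_range, W = exp(log_w_data), log_W = log_w_data,
                  E_log_W = e_log_w, gap = gap, s = s)
  D <- compute_distance(v, metric)
  structure(list(
    curve = curve,
    chosen_k = chosen,
    argmax_k = k_range[which.max(gap)],
    B = B, seed = seed,
    fit = kmedoids_fit(D, chosen)
  ), class = "gap_curve")
}

#' @export
print.gap_curve <- function(x, ...) {
  cat(sprintf("<gap_curve> k in [%d, %d], chosen k = %d (one-SE), argmax k = %d\n",
              min(x$curve$k), max(x$curve$k), x$chosen_k, x$argmax_k))
  invisible(x)
}

#' Match two clusterings by optimal label assignment
#'
#' Maps the labels of a new clustering onto a reference clustering by
#' maximum-overlap one-to-one assignment (Hungarian method on the
#' contingency table), over the samples the two share. Surplus labels on
#' either side stay unmapped and count as mismatches.
#'
#' @param reference,new named cluster-assignment vectors (names are sample
#'   ids) or `clustering_result` objects.
#' @return A list: `mapping` (new label -> reference label, `NA` when
#'   unmapped), `matched_fraction`, `n_shared`.
#' @export
match_clusters <- function(reference, new) {
  ref <- if (inherits(reference, "clustering_result")) reference$assignment else reference
  nw <- if (inherits(new, "clustering_result")) new$assignment else new
  shared <- intersect(names(ref), names(nw))
  if (length(shared) == 0L) abort_vagmet("clusterings share no samples")
  r <- as.character(ref[shared])
  w <- as.character(nw[shared])
  r_lev <- sort(unique(r))
  w_lev <- sort(unique(w))
  counts <- table(factor(w, levels = w_lev), factor(r, levels = r_lev))
  assign_col <- assignment_max(unclass(counts))
  mapping <- setNames(rep(NA_character_, length(w_lev)), w_lev)
  for (i in seq_along(w_lev)) {
    if (!is.na(assign_col[i])) mapping[i] <- r_lev[assign_col[i]]
  }
  mapped <- mapping[w]
  matched <- sum(!is.na(mapped) & mapped == r)
  list(mapping = mapping,
       matched_fraction = matched / length(shared),
       n_shared = length(shared))
}

#' Subsample robustness of a reference clustering
#'
#' Redraws `round(fraction * n)` samples without replacement
#' `n_subsamples` times, reclusters each subset de novo at the reference
#' `k` on the corresponding sub-distance-matrix, and scores each refit
#' against the reference assignment restricted to the subset via
#' [match_clusters()].
#'
#' @param d `vm_dist` over the full cohort (the metric the reference was
#'   fitted with).
#' @param reference `clustering_result` fitted on the full data.
#' @param n_subsamples number of random subsets.
#' @param fraction subset size as a fraction of the cohort, in `(0, 1]`.
#' @param seed integer seed; subsample draws come from a dedicated
#'   substream so the report is bit-reproducible given `(seed,
#'   n_subsamples)`.
#' @return A `robustness_report`: per-subsample accuracies,
#'   `mean_accuracy`, and `n_above_95` (count strictly above 0.95).
#' @export
cluster_robustness <- function(d, reference, n_subsamples = 100L, fraction = 0.9,
                               seed = 1L) {
  D <- if (inherits(d, "vm_dist")) d$D else as.matrix(d)
  if (fraction <= 0 || fraction > 1) abort_vagmet("fraction must lie in (0, 1]")
  n <- nrow(D)
  m <- round(fraction * n)
  acc <- numeric(n_subsamples)
  with_seed(substream_seed(seed, "robustness"), {
    for (b in seq_len(n_subsamples)) {
      idx <- sort(sample.int(n, m))
      sub <- D[idx, idx, drop = FALSE]
      refit <- kmedoids_fit(sub, reference$k)
      acc[b] <- match_clusters(reference$assignment[rownames(sub)],
                               refit$assignment)$matched_fraction
    }
  })
  structure(list(
    n_subsamples = n_subsamples,
    subsample_fraction = fraction,
    accuracies = acc,
    mean_accuracy = mean(acc),
    n_above_95 = sum(acc > 0.95),
    seed = seed
  ), class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "<robustness_report> %d subsamples of %.0f%%: mean accuracy %.1f%%, %d above 95%%\n",
    x$n_subsamples, 100 * x$subsample_fraction, 100 * x$mean_accuracy, x$n_above_95
  ))
  invisible(x)
}

#' One-vs-rest Fisher exact associations between two categorical labellings
#'
#' For every pair of levels (one from each labelling), a two-sided Fisher
#' exact test on the 2x2 one-vs-rest table, with Benjamini-Hochberg
#' q-values across all tests performed within the call.
#'
#' @param labels_a,labels_b categorical vectors over the same samples.
#' @param scope optional logical filter restricting the samples considered.
#' @return A tibble: `level_a`, `level_b`, the 2x2 counts (`n11`, `n10`,
#'   `n01`, `n00`), `odds_ratio`, `p`, `q`. Levels with zero members after
#'   filtering are skipped and listed in attribute `skipped`.
#' @export
contingency_association <- function(labels_a, labels_b, scope = NULL) {
  if (length(labels_a) != length(labels_b)) abort_vagmet("label vectors differ in length")
  if (!is.null(scope)) {
    labels_a <- labels_a[scope]
    labels_b <- labels_b[scope]
  }
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  lev_a <- sort(unique(a))
  lev_b <- sort(unique(b))
  skipped <- character()
  rows <- list()
  for (la in lev_a) {
    for (lb in lev_b) {
      ia <- a == la
      ib <- b == lb
      tab <- matrix(c(sum(ia & ib), sum(ia & !ib), sum(!ia & ib), sum(!ia & !ib)),
                    nrow = 2L)
      if (sum(ia) == 0L || sum(ib) == 0L) {
        skipped <- c(skipped, sprintf("%s/%s: empty level", la, lb))
        next
      }
      ft <- fisher.test(tab)
      rows[[length(rows) + 1L]] <- tibble(
        level_a = la, level_b = lb,
        n11 = tab[1, 1], n10 = tab[1, 2], n01 = tab[2, 1], n00 = tab[2, 2],
        odds_ratio = unname(ft$estimate), p = ft$p.value
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0L) out$q <- bh_fdr(out$p)
  attr(out, "skipped") <- skipped
  out
}
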