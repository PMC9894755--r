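#' Build metabolite sets from feature annotations
#'
#' One set per distinct sub-pathway, super-pathway, and KEGG pathway with at
#' least two annotated members. Features lacking KEGG identifiers are
#' excluded from KEGG sets only; they still contribute to pathway sets via
#' their sub- and super-pathway.
#'
#' @param annotations tibble with `feature_id`, `super_pathway`,
#'   `sub_pathway`, and optionally `kegg_ids` (semicolon-separated string or
#'   list column of KEGG pathway ids).
#' @param min_size smallest admissible set.
#' @return A tibble: `set_id`, `set_type` (`super_pathway`, `sub_pathway`,
#'   `kegg_pathway`), `members` (list column of feature ids), `n_members`.
#' @export
build_metabolite_sets <- function(annotations, min_size = 2L) {
  sets <- list()
  harvest <- function(values, type) {
    ok <- !is.na(values) & values != ""
    for (lev in sort(unique(values[ok]))) {
      members <- sort(unique(annotations$feature_id[ok & values == lev]))
      if (length(members) >= min_size) {
        sets[[length(sets) + 1L]] <<- tibble(
          set_id = lev, set_type = type,
          members = list(members), n_members = length(members)
        )
      }
    }
  }
  if ("super_pathway" %in% names(annotations)) {
    harvest(as.character(annotations$super_pathway), "super_pathway")
  }
  if ("sub_pathway" %in% names(annotations)) {
    harvest(as.character(annotations$sub_pathway), "sub_pathway")
  }
  if ("kegg_ids" %in% names(annotations)) {
    kegg <- annotations$kegg_ids
    if (!is.list(kegg)) kegg <- strsplit(ifelse(is.na(kegg), "", kegg), ";", fixed = TRUE)
    pairs <- tibble(
      feature_id = rep(annotations$feature_id, lengths(kegg)),
      kegg = unlist(kegg)
    ) |> filter(.data$kegg != "")
    if (nrow(pairs) > 0L) {
      for (lev in sort(unique(pairs$kegg))) {
        members <- sort(unique(pairs$feature_id[pairs$kegg == lev]))
        if (length(members) >= min_size) {
          sets[[length(sets) + 1L]] <- tibble(
            set_id = lev, set_type = "kegg_pathway",
            members = list(members), n_members = length(members)
          )
        }
      }
    }
  }
  bind_rows(sets)
}

# One-sided (in-set stochastically smaller) second-level Mann-Whitney
# p-values for every set under every column of a p-value matrix.
# `pmat`: features x columns; `member`: features x sets indicator.
second_level_p <- function(pmat, member, n_in, n_out) {
  n_feat <- nrow(pmat) # identical universe for every set
  rk <- apply(pmat, 2L, rank, ties.method = "average")   # features x cols
  r_in <- crossprod(member, rk)                          # sets x cols
  u <- r_in - n_in * (n_in + 1) / 2
  mu <- n_in * n_out / 2
  # tie correction per column (p-value ties are rare but possible)
  tie <- apply(pmat, 2L, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  })
  term <- (n_feat + 1) - tie / (n_feat * (n_feat - 1)) # length = columns
  sig2 <- outer(n_in * n_out / 12, term)
  z <- (u - mu + 0.5) / sqrt(pmax(sig2, .Machine$double.eps))
  pnorm(z) # P(U <= u): small when in-set p-values rank low
}

#' Permutation-null metabolite-set enrichment scan
#'
#' Tests whether the metabolites of a functional set are enriched for
#' outcome associations. The observed statistic for a set is the one-sided
#' second-level Mann-Whitney p-value comparing the per-feature association
#' p-values inside the set with those outside it (small when in-set
#' p-values are stochastically smaller). Its significance is calibrated
#' against the same statistic recomputed under `n_permutations` random
#' relabellings of the outcome within the stratum:
#' `perm_p = (1 + #\{null <= observed\}) / (1 + n_permutations)`.
#'
#' The prevalence filter is applied once to the observed stratum and the
#' resulting feature universe is held fixed across permutations (label
#' shuffles do not change detection masks), and the per-feature p-values
#' inside the permutation loop come from the same code path as the observed
#' scan. All sets within a call share one permutation stream, so their
#' results are mutually comparable; per-feature null scans are computed
#' once and reused by every set.
#'
#' @param mat a [metab_matrix()] (raw or log scale).
#' @param metadata a [cohort_metadata()] tibble.
#' @param sets tibble from [build_metabolite_sets()].
#' @param stratum a single stratum name (see [default_strata()]) or a
#'   definition list with `filter` and `case`.
#' @param n_permutations label permutations for the null.
#' @param seed integer master seed for the permutation stream.
#' @param min_prevalence detection-fraction filter for the underlying scan.
#' @param sided `"one"` (default; enrichment is directional) or `"two"`
#'   for a symmetric second-level test.
#' @return A tibble of enrichment records: `set_id`, `set_type`, `stratum`,
#'   `observed_second_level_p`, `perm_p`, `q` (within `set_type`), `n_in`,
#'   `n_out`, `n_permutations`, `seed`.
#' @export
set_enrichment_scan <- function(mat, metadata, sets, stratum = "all",
                                n_permutations = 10000L, seed = 1L,
                                min_prevalence = 0.5, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(inherits(mat, "metab_matrix"))
  metadata <- cohort_metadata(metadata)
  ids <- sample_ids(mat)
  metadata <- metadata[match(ids, metadata$sample_id), ]
  if (is.character(stratum)) {
    st <- default_strata(metadata)[[stratum]]
    if (is.null(st)) abort_vagmet(sprintf("unknown stratum: %s", stratum))
    stratum_label <- stratum
  } else {
    st <- stratum
    stratum_label <- st$label %||% "custom"
  }
  filt <- st$filter
  case <- st$case[filt]
  if (length(unique(case)) < 2L || sum(case) < 3L || sum(!case) < 3L) {
    abort_vagmet("degenerate stratum for enrichment (need >= 3 per class)")
  }
  v <- mat$values[filt, , drop = FALSE]

  # fixed feature universe: prevalence and non-constancy on the observed stratum
  keep_frac <- colMeans(!is.na(v))
  nonconst <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j][!is.na(v[, j])]
    length(unique(x)) >= 2L
  }, logical(1L))
  tested <- keep_frac >= min_prevalence & nonconst
  v <- v[, tested, drop = FALSE]
  universe <- colnames(v)
  n_feat <- length(universe)
  if (n_feat < 4L) abort_vagmet("too few tested features for a second-level contrast")

  member <- vapply(sets$members, function(m) universe %in% m, logical(n_feat))
  member <- matrix(as.numeric(member), nrow = n_feat)
  n_in <- colSums(member)
  n_out <- n_feat - n_in
  usable <- n_in >= 2L & n_out >= 2L
  if (any(n_out == 0L & n_in > 0L)) {
    abort_vagmet("a set covers every tested feature (empty out-set)")
  }
  if (!any(usable)) abort_vagmet("no set has >= 2 tested members and >= 2 non-members")

  # observed labels + permuted labels as one indicator matrix: the full scan
  # runs through mw_scan for every column identically
  n_s <- nrow(v)
  perm <- matrix(NA_real_, nrow = n_s, ncol = n_permutations + 1L)
  perm[, 1L] <- as.numeric(case)
  with_seed(substream_seed(seed, paste0("enrichment_", stratum_label)), {
    for (b in seq_len(n_permutations)) perm[, b + 1L] <- as.numeric(sample(case))
  })
  prep <- mw_prep(v)
  pmat <- mw_scan(prep, perm)$p # features x (1 + B)

  mem_use <- member[, usable, drop = FALSE]
  sl <- second_level_p(pmat, mem_use, n_in[usable], n_out[usable])
  if (sided == "two") {
    sl <- pmin(1, 2 * pmin(sl, 1 - sl))
  }
  obs <- sl[, 1L]
  null <- sl[, -1L, drop = FALSE]
  perm_p <- (1 + rowSums(null <= obs)) / (1 + n_permutations)

  out <- tibble(
    set_id = sets$set_id[usable],
    set_type = sets$set_type[usable],
    stratum = stratum_label,
    observed_second_level_p = unname(obs),
    perm_p = unname(perm_p),
    n_in = as.integer(n_in[usable]),
    n_out = as.integer(n_out[usable]),
    n_permutations = n_permutations,
    seed = seed
  )
  out$q <- bh_fdr(out$perm_p, group = out$set_type)
  out[, c("set_id", "set_type", "stratum", "observed_second_level_p",
          "perm_p", "q", "n_in", "n_out", "n_permutations", "seed")]
}
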