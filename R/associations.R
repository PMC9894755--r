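#' Benjamini-Hochberg q-values, optionally within groups
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param group optional grouping vector; the step-up correction is applied
#'   within each group independently.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p, group = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_vagmet("p-values must lie in [0, 1]")
  if (is.null(group)) return(p.adjust(p, method = "BH"))
  q <- rep(NA_real_, length(p))
  for (g in unique(group)) {
    i <- which(group == g)
    q[i] <- p.adjust(p[i], method = "BH")
  }
  q
}

#' Default outcome strata for the association scans
#'
#' Builds the scan strata used throughout: the full cohort, each major race
#' group, the progesterone-free subsets, and the early-delivery contrasts
#' (before 32 and before 28 weeks), which are restricted to Black women
#' because early deliveries concentrate in that group.
#'
#' @param metadata a [cohort_metadata()] tibble.
#' @param early_controls `"all_other"` (controls are all other births in the
#'   stratum, default) or `"term_only"` for the early-delivery contrasts.
#' @return Named list of stratum definitions (each with `filter` and `case`
#'   logical vectors over the metadata rows).
#' @export
default_strata <- function(metadata, early_controls = c("all_other", "term_only")) {
  early_controls <- match.arg(early_controls)
  sptb <- metadata$outcome == "sPTB"
  black <- metadata$race == "Black"
  white <- metadata$race == "White"
  strata <- list(
    all = list(filter = rep(TRUE, nrow(metadata)), case = sptb),
    Black = list(filter = black, case = sptb),
    White = list(filter = white, case = sptb)
  )
  if ("progesterone" %in% names(metadata)) {
    nop <- !metadata$progesterone
    strata$no_progesterone_Black <- list(filter = nop & black, case = sptb)
    strata$no_progesterone_White <- list(filter = nop & white, case = sptb)
  }
  for (cut in c(32, 28)) {
    case <- metadata$gab_weeks < cut
    filt <- if (early_controls == "all_other") black else black & (case | metadata$outcome == "TB")
    strata[[sprintf("GAB<%d_Black", cut)]] <- list(filter = filt, case = case)
  }
  strata
}

# Internal single-stratum scan on a raw/log-scale values matrix.
scan_one_stratum <- function(values, case, stratum_label, min_prevalence, exact_max) {
  keep_frac <- colMeans(!is.na(values))
  tested <- keep_frac >= min_prevalence
  # constant-observed features cannot be ranked informatively
  const <- vapply(seq_len(ncol(values)), function(j) {
    x <- values[, j][!is.na(values[, j])]
    length(unique(x)) < 2L
  }, logical(1L))
  out_idx <- which(!tested | (tested & const))
  excluded <- tibble(
    feature_id = colnames(values)[out_idx],
    stratum = rep(stratum_label, length(out_idx)),
    reason = ifelse(!tested[out_idx],
                    sprintf("detection fraction below %.2f", min_prevalence),
                    "constant within stratum")
  )
  excluded$reason <- as.character(excluded$reason)
  tested <- tested & !const
  if (!any(tested)) {
    return(list(records = tibble(), excluded = excluded))
  }
  v <- values[, tested, drop = FALSE]
  prep <- mw_prep(v)
  res <- mw_scan(prep, matrix(as.numeric(case), ncol = 1L))
  u <- res$U[, 1L]
  p <- res$p[, 1L]
  n1 <- res$n1[, 1L]
  n2 <- res$n2[, 1L]
  # exact enumeration where the product of group sizes is small and the
  # feature has no ties (matching the classical exact null)
  for (j in seq_len(ncol(v))) {
    if (n1[j] > 0 && n2[j] > 0 && n1[j] * n2[j] <= exact_max &&
        prep$tie_term[j] == 0) {
      p[j] <- mw_exact_p(u[j], n1[j], n2[j])
    }
  }
  med_case <- apply(v[case, , drop = FALSE], 2L, median, na.rm = TRUE)
  med_ctrl <- apply(v[!case, , drop = FALSE], 2L, median, na.rm = TRUE)
  records <- tibble(
    feature_id = colnames(v),
    stratum = stratum_label,
    U = unname(u),
    p = unname(p),
    q = bh_fdr(unname(p)),
    direction = unname(sign(med_case - med_ctrl)),
    n_case = as.integer(n1),
    n_ctrl = as.integer(n2),
    prevalence = unname(keep_frac[tested])
  )
  list(records = records, excluded = excluded)
}

#' Stratified per-metabolite differential-abundance scan
#'
#' Two-sided Mann-Whitney U tests between outcome groups, computed on
#' observed values only (missing cells drop out of the ranks; no
#' imputation). Within each stratum, features detected in fewer than
#' `min_prevalence` of the stratum's samples are excluded before testing,
#' and Benjamini-Hochberg q-values are computed across the features that
#' were tested. Exact enumeration replaces the tie-corrected normal
#' approximation when `n_case * n_ctrl <= exact_max` and the feature has no
#' ties.
#'
#' @param mat a [metab_matrix()] (raw or log scale; the statistic is
#'   rank-based so any monotone scale gives identical results).
#' @param metadata a [cohort_metadata()] tibble aligned to the matrix by
#'   `sample_id`.
#' @param strata a named list from [default_strata()], a subset of its
#'   names, or `"all"` for the plain sPTB-vs-term scan.
#' @param min_prevalence minimum within-stratum detection fraction.
#' @param exact_max largest `n_case * n_ctrl` for the exact branch.
#' @return A tibble of association records (`feature_id`, `stratum`, `U`,
#'   `p`, `q`, `direction`, `n_case`, `n_ctrl`, `prevalence`), with
#'   attributes `excluded` (filtered features with reasons) and `skipped`
#'   (strata that failed size preconditions, when several were requested).
#' @export
association_scan <- function(mat, metadata, strata = "all",
                             min_prevalence = 0.5, exact_max = 400L) {
  stopifnot(inherits(mat, "metab_matrix"))
  metadata <- cohort_metadata(metadata)
  ids <- sample_ids(mat)
  if (!setequal(ids, metadata$sample_id)) {
    abort_vagmet("matrix and metadata must cover the same samples")
  }
  metadata <- metadata[match(ids, metadata$sample_id), ]
  if (is.character(strata)) {
    all_strata <- default_strata(metadata)
    missing_strata <- setdiff(strata, names(all_strata))
    if (length(missing_strata) > 0L) {
      abort_vagmet(sprintf("unknown stratum: %s", paste(missing_strata, collapse = ", ")))
    }
    strata <- all_strata[strata]
  }
  single <- length(strata) == 1L
  records <- list()
  excluded <- list()
  skipped <- character()
  for (nm in names(strata)) {
    st <- strata[[nm]]
    filt <- st$filter
    case <- st$case[filt]
    if (sum(filt) == 0L || length(unique(case)) < 2L) {
      if (single) abort_vagmet(sprintf("stratum '%s' is empty or single-class", nm))
      skipped <- c(skipped, nm)
      next
    }
    if (sum(case) < 3L || sum(!case) < 3L) {
      if (single) {
        abort_vagmet(sprintf("stratum '%s' needs >= 3 cases and >= 3 controls", nm))
      }
      skipped <- c(skipped, nm)
      next
    }
    one <- scan_one_stratum(mat$values[filt, , drop = FALSE], case, nm,
                            min_prevalence, exact_max)
    records[[nm]] <- one$records
    excluded[[nm]] <- one$excluded
  }
  out <- bind_rows(records)
  attr(out, "excluded") <- bind_rows(excluded)
  attr(out, "skipped") <- skipped
  out
}

#' Rank features by average signed log p across strata
#'
#' Per feature, the mean over the strata where it was tested of
#' `direction * (-log10 p)`; features are returned in descending order of
#' this score (case-enriched, consistently significant features first),
#' ties broken lexicographically by feature id.
#'
#' @param records association tibble from [association_scan()].
#' @return A tibble (`feature_id`, `score`, `n_strata`), ordered.
#' @export
rank_by_signed_logp <- function(records) {
  if (nrow(records) == 0L) return(tibble(feature_id = character(), score = numeric(), n_strata = integer()))
  records |>
    mutate(signed = .data$direction * (-log10(pmax(.data$p, .Machine$double.xmin)))) |>
    group_by(.data$feature_id) |>
    summarise(score = mean(.data$signed), n_strata = dplyr::n(), .groups = "drop") |>
    arrange(desc(.data$score), .data$feature_id)
}
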