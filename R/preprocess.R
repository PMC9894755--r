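#' Volume-normalize raw metabolite measurements
#'
#' Divides each sample's observed values by the volume of extraction buffer
#' used for that sample. The matrix stays on the raw scale and the
#' missingness mask is untouched.
#'
#' @param mat a raw-scale [metab_matrix()].
#' @param volumes named positive numeric vector, one entry per sample.
#' @return A raw-scale [metab_matrix()].
#' @export
volume_normalize <- function(mat, volumes) {
  stopifnot(inherits(mat, "metab_matrix"))
  if (mat$scale_tag != "raw") abort_vagmet("volume normalization expects a raw-scale matrix")
  ids <- sample_ids(mat)
  if (is.null(names(volumes))) names(volumes) <- ids
  if (!all(ids %in% names(volumes))) {
    abort_vagmet("a volume is required for every sample")
  }
  v <- volumes[ids]
  if (any(!is.finite(v)) || any(v <= 0)) abort_vagmet("volumes must be positive and finite")
  metab_matrix(sweep(mat$values, 1L, v, "/"), scale_tag = "raw")
}

#' Base-10 log transform
#'
#' @param mat a raw-scale [metab_matrix()] with strictly positive observed
#'   values.
#' @return A `log10`-scale [metab_matrix()]; the mask is unchanged.
#' @export
log10_transform <- function(mat) {
  stopifnot(inherits(mat, "metab_matrix"))
  if (mat$scale_tag != "raw") abort_vagmet("log transform expects a raw-scale matrix")
  if (any(mat$values <= 0, na.rm = TRUE)) {
    abort_vagmet("raw detections must be strictly positive; zero/negative value found")
  }
  out <- mat
  out$values <- log10(mat$values)
  out$scale_tag <- "log10"
  out
}

# SD of x after removing the top and bottom ceil(trim * n) order statistics,
# with the n-1 denominator on the retained values.
trimmed_sd <- function(x, trim = 0.05) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  k <- ceiling(trim * n)
  keep <- x[seq.int(k + 1L, n - k)]
  sd(keep)
}

#' Robust per-feature standardization
#'
#' For each feature, subtracts the median of the observed values and divides
#' by a trimmed standard deviation: the SD of the values that remain after
#' excluding the top and bottom `ceil(trim * n)` order statistics. This
#' outlier-clipped dispersion keeps single extreme measurements from
#' deflating every other sample's standardized level. Features whose trimmed
#' SD is zero (effectively constant) are excluded with a reason rather than
#' silently zeroed.
#'
#' @param mat a `log10`-scale [metab_matrix()] with at least 3 observed
#'   values per feature.
#' @param trim fraction trimmed per tail when computing the SD.
#' @return A `standardized` [metab_matrix()] with attribute `excluded`, a
#'   tibble of dropped features and reasons.
#' @export
robust_standardize <- function(mat, trim = 0.05) {
  stopifnot(inherits(mat, "metab_matrix"))
  if (mat$scale_tag != "log10") abort_vagmet("robust standardization expects log10 values")
  v <- mat$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 3L)) {
    abort_vagmet(sprintf(
      "feature(s) with fewer than 3 observed values: %s",
      paste(head(colnames(v)[n_obs < 3L], 5L), collapse = ", ")
    ))
  }
  med <- apply(v, 2L, median, na.rm = TRUE)
  tsd <- apply(v, 2L, trimmed_sd, trim = trim)
  drop <- !is.finite(tsd) | tsd == 0
  excluded <- tibble(
    feature_id = colnames(v)[drop],
    reason = "zero trimmed dispersion (constant feature)"
  )
  keep <- !drop
  out <- sweep(sweep(v[, keep, drop = FALSE], 2L, med[keep], "-"), 2L, tsd[keep], "/")
  res <- mat
  res$values <- out
  res$scale_tag <- "standardized"
  attr(res, "excluded") <- excluded
  res
}

#' Detection summary of a metabolite matrix
#'
#' Counts features by how often they are detected: the per-feature detection
#' fraction is the share of samples with an observed (unmasked) value.
#' "Detected in over half" uses a strict `> 0.5`; "detected in all" means no
#' masked entry. Counts are reported over all features and, when annotations
#' are supplied, over the named subset as a second denominator.
#'
#' @param mat a [metab_matrix()] (any scale; the summary depends only on
#'   the mask).
#' @param annotations optional annotation tibble with `feature_id` and
#'   `named_flag`.
#' @return A list of class `detection_summary`.
#' @export
detection_summary <- function(mat, annotations = NULL) {
  stopifnot(inherits(mat, "metab_matrix"))
  obs <- !is.na(mat$values)
  frac <- colMeans(obs)
  named <- rep(TRUE, ncol(mat$values))
  if (!is.null(annotations) && nrow(annotations) > 0L && "named_flag" %in% names(annotations)) {
    named <- colnames(mat$values) %in% annotations$feature_id[annotations$named_flag]
  }
  structure(list(
    n_features_total = ncol(mat$values),
    n_named = sum(named),
    n_unnamed = sum(!named),
    detection_fraction = tibble(feature_id = colnames(mat$values),
                                fraction = unname(frac), named = named),
    n_detected_over_half = sum(frac > 0.5),
    n_detected_in_all = sum(frac == 1),
    n_detected_over_half_named = sum(frac > 0.5 & named),
    n_detected_in_all_named = sum(frac == 1 & named)
  ), class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf(
    "<detection_summary> %d features (%d named, %d unnamed); %d detected in >50%% of samples, %d in all\n",
    x$n_features_total, x$n_named, x$n_unnamed,
    x$n_detected_over_half, x$n_detected_in_all
  ))
  invisible(x)
}

#' Detection-limit (per-feature minimum) imputation
#'
#' Replaces each masked cell with the minimum observed value of its feature,
#' the usual surrogate under left-censored, detection-limit missingness.
#' Used where a complete matrix is required (distance computation,
#' prediction features); correlation analyses never impute.
#'
#' @param mat a [metab_matrix()] with at least one observed value per
#'   feature.
#' @return A complete [metab_matrix()] with attribute `imputed`, the logical
#'   mask of filled cells.
#' @export
min_impute <- function(mat) {
  stopifnot(inherits(mat, "metab_matrix"))
  v <- mat$values
  none <- colSums(!is.na(v)) == 0L
  if (any(none)) {
    abort_vagmet(sprintf(
      "feature(s) with no observed values cannot be imputed: %s",
      paste(head(colnames(v)[none], 5L), collapse = ", ")
    ))
  }
  mask <- is.na(v)
  mins <- apply(v, 2L, min, na.rm = TRUE)
  fill <- matrix(mins, nrow = nrow(v), ncol = ncol(v), byrow = TRUE)
  v[mask] <- fill[mask]
  out <- mat
  out$values <- v
  attr(out, "imputed") <- mask
  out
}

#' Standard preprocessing chain for clustering and distances
#'
#' Raw values -> optional volume normalization -> log10 -> robust
#' standardization -> per-feature minimum imputation, giving the complete
#' standardized matrix downstream structure analyses consume.
#'
#' @param mat raw [metab_matrix()].
#' @param volumes optional per-sample buffer volumes.
#' @inheritParams robust_standardize
#' @return A complete, standardized [metab_matrix()].
#' @export
preprocess_pipeline <- function(mat, volumes = NULL, trim = 0.05) {
  if (!is.null(volumes)) mat <- volume_normalize(mat, volumes)
  min_impute(robust_standardize(log10_transform(mat), trim = trim))
}
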