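#' Tidy a gap-statistic curve
#'
#' @param x a `gap_curve` from [select_k_gap()].
#' @param ... unused.
#' @return The per-k tibble (`k`, `W`, `log_W`, `E_log_W`, `gap`, `s`).
#' @export
tidy.gap_curve <- function(x, ...) x$curve

#' @rdname tidy.gap_curve
#' @export
glance.gap_curve <- function(x, ...) {
  tibble(chosen_k = x$chosen_k, argmax_k = x$argmax_k, B = x$B, seed = x$seed)
}

#' Tidy a clustering result
#'
#' @param x a `clustering_result` from [kmedoids_fit()].
#' @param ... unused.
#' @return One row per sample: `sample_id`, `cluster`, `is_medoid`.
#' @export
tidy.clustering_result <- function(x, ...) {
  tibble(
    sample_id = names(x$assignment),
    cluster = unname(x$assignment),
    is_medoid = names(x$assignment) %in% x$medoid_ids
  )
}

#' @rdname tidy.clustering_result
#' @export
glance.clustering_result <- function(x, ...) {
  tibble(k = x$k, W = x$W, n = length(x$assignment))
}

#' Tidy a subsample robustness report
#'
#' @param x a `robustness_report` from [cluster_robustness()].
#' @param ... unused.
#' @return One row per subsample with its matched-assignment accuracy.
#' @export
tidy.robustness_report <- function(x, ...) {
  tibble(subsample = seq_len(x$n_subsamples), accuracy = x$accuracies)
}

#' @rdname tidy.robustness_report
#' @export
glance.robustness_report <- function(x, ...) {
  tibble(
    n_subsamples = x$n_subsamples,
    subsample_fraction = x$subsample_fraction,
    mean_accuracy = x$mean_accuracy,
    n_above_95 = x$n_above_95
  )
}

#' Tidy a PERMANOVA result
#'
#' @param x a `permanova_result`.
#' @param ... unused.
#' @return A one-row tibble with `pseudo_F`, `p`, `n_permutations`.
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, p = x$p, n_permutations = x$n_permutations)
}

#' Tidy a nested-CV prediction report
#'
#' @param x a `prediction_report` from [nested_cv()].
#' @param ... unused.
#' @return One row per (sample, repeat): out-of-fold score and label.
#' @export
tidy.prediction_report <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$scores))
  names(out) <- paste0("repeat_", seq_len(ncol(x$scores)))
  out$sample_id <- x$sample_ids
  out$label <- x$labels
  tidyr::pivot_longer(out, dplyr::starts_with("repeat_"),
                      names_to = "repeat_i", names_prefix = "repeat_",
                      values_to = "score") |>
    mutate(repeat_i = as.integer(.data$repeat_i))
}

#' @rdname tidy.prediction_report
#' @export
glance.prediction_report <- function(x, ...) {
  tibble(
    outcome_def = x$outcome_def,
    auroc = x$auroc,
    aupr = x$aupr,
    n_repeats = ncol(x$scores),
    n_samples = nrow(x$scores),
    learner = x$learner_name
  )
}

#' Tidy a detection summary
#'
#' @param x a `detection_summary`.
#' @param ... unused.
#' @return Per-feature detection fractions.
#' @export
tidy.detection_summary <- function(x, ...) x$detection_fraction

#' @rdname tidy.detection_summary
#' @export
glance.detection_summary <- function(x, ...) {
  tibble(
    n_features_total = x$n_features_total,
    n_named = x$n_named,
    n_unnamed = x$n_unnamed,
    n_detected_over_half = x$n_detected_over_half,
    n_detected_in_all = x$n_detected_in_all
  )
}
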