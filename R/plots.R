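#' Plot a gap-statistic curve
#'
#' Gap against k with one-SE error bars; the chosen k (one-SE rule) is
#' marked.
#'
#' @param object a `gap_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gap_curve <- function(object, ...) {
  d <- object$curve
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$s,
                                          ymax = .data$gap + .data$s)) +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "number of clusters k", y = "Gap(k)",
                  title = sprintf("Gap statistic (chosen k = %d)", object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' Plot ROC curves of a prediction report
#'
#' Per-repeat pooled out-of-fold ROC curves with the chance diagonal.
#'
#' @param object a `prediction_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_report <- function(object, ...) {
  curves <- lapply(seq_len(ncol(object$scores)), function(r) {
    d <- roc_points(object$scores[, r], object$labels)
    d$repeat_i <- factor(r)
    d
  })
  d <- bind_rows(curves)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                  colour = .data$repeat_i)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      colour = "repeat",
      title = sprintf("%s: mean auROC = %.2f", object$outcome_def, object$auroc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a microbe-metabolite edge map
#'
#' Kept edges as a taxon x metabolite tile map coloured by Spearman
#' correlation.
#'
#' @param edges edge tibble from [correlation_network()].
#' @param kept_only show only edges passing the thresholds.
#' @return A ggplot object.
#' @export
plot_network_edges <- function(edges, kept_only = TRUE) {
  d <- if (kept_only) filter(edges, .data$kept) else edges
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature_id, y = .data$taxon_id,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Volcano-style plot of an association scan
#'
#' Signed effect direction times -log10(p), coloured by q-value threshold.
#'
#' @param records association tibble from [association_scan()].
#' @param q_max significance threshold for colouring.
#' @return A ggplot object.
#' @export
plot_associations <- function(records, q_max = 0.1) {
  d <- mutate(records,
              signed_logp = .data$direction * -log10(pmax(.data$p, 1e-300)),
              significant = .data$q < q_max)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed_logp, y = -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~.data$stratum) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "direction x -log10 p", y = "-log10 p",
                  colour = sprintf("q < %.2g", q_max)) +
    ggplot2::theme_minimal()
}
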