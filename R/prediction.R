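#' Area under the ROC curve by rank statistic
#'
#' Midrank (tie-averaging) formulation: equals the concordant-pair fraction
#' with ties counted half. All scores equal gives 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) abort_vagmet("auROC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration of precision over recall at every distinct score
#' threshold, descending.
#'
#' @inheritParams auroc
#' @return auPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (sum(y) == 0L) abort_vagmet("auPR needs positive examples")
  o <- order(scores, decreasing = TRUE)
  y <- y[o]
  s <- scores[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE) # last index of each threshold block
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

roc_points <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  o <- order(scores, decreasing = TRUE)
  y <- y[o]
  s <- scores[o]
  last <- !duplicated(s, fromLast = TRUE)
  tibble(
    threshold = s[last],
    tpr = cumsum(y)[last] / sum(y),
    fpr = cumsum(1 - y)[last] / sum(1 - y)
  )
}

r_squared <- function(scores, labels) {
  y <- as.numeric(as.logical(labels))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - scores)^2) / sst
}

binary_stratum_key <- function(metadata, composite = TRUE) {
  if (!composite) return(rep("all", nrow(metadata)))
  ifelse(metadata$race == "Black", "Black", "nonBlack")
}

#' Fit a race-composite predictor
#'
#' Fits one feature pipeline + learner per stratum (default `{Black,
#' non-Black}`) on the training rows of that stratum only; a sample is
#' always scored by exactly its own stratum's model. With a single-stratum
#' key this reduces to a plain (non-composite) pipeline.
#'
#' @param fs a [build_feature_set()] object.
#' @param metadata cohort metadata aligned to the feature set.
#' @param hp one hyperparameter row (list or one-row tibble).
#' @param learner a learner object ([xgb_learner()] default).
#' @param train_idx integer indices of the training samples.
#' @param composite use the binary race grouping (`TRUE`) or one pooled
#'   model.
#' @param seed integer seed passed to the learner.
#' @return A `composite_predictor`.
#' @export
fit_composite <- function(fs, metadata, hp, learner = xgb_learner(),
                          train_idx = seq_len(nrow(metadata)),
                          composite = TRUE, seed = 1L) {
  metadata <- cohort_metadata(metadata)
  hp <- as.list(hp)
  y <- as.integer(metadata$outcome == "sPTB")
  key <- binary_stratum_key(metadata, composite)
  pipes <- list()
  for (lev in sort(unique(key))) {
    s_idx <- which(key == lev)
    s_train <- intersect(train_idx, s_idx)
    ys <- y[s_train]
    if (length(unique(ys)) < 2L) {
      abort_vagmet(sprintf("stratum '%s' has a single outcome class in training data", lev))
    }
    # context local to the stratum: no statistic sees another stratum or test rows
    local_train <- match(s_train, s_idx)
    ctx <- make_fold_ctx(subset_feature_set(fs, s_idx), y[s_idx], local_train)
    pipes[[lev]] <- fit_pipe(ctx, hp, learner, substream_seed(seed, paste0("fit_", lev)))
  }
  structure(list(
    pipes = pipes, stratum_key = key, learner = learner,
    hp = hp, sample_ids = metadata$sample_id, composite = composite
  ), class = "composite_predictor")
}

# Restrict a feature set to a sample subset (indices into its rows).
subset_feature_set <- function(fs, idx) {
  out <- fs
  out$sample_ids <- fs$sample_ids[idx]
  switch(fs$type,
    clinical = { out$X <- fs$X[idx, , drop = FALSE] },
    metabolome = { out$X <- fs$X[idx, , drop = FALSE] },
    microbiome = {
      out$rel <- fs$rel[idx, , drop = FALSE]
      out$load <- fs$load[idx]
    },
    combined = { out$parts <- lapply(fs$parts, subset_feature_set, idx = idx) }
  )
  out
}

#' Score samples with a composite predictor
#'
#' @param object a `composite_predictor`.
#' @param fs the feature set the predictor was built from (or a compatible
#'   one over the samples to score).
#' @param idx row indices to score (default all).
#' @param ... unused.
#' @return Numeric scores named by sample id.
#' @export
predict.composite_predictor <- function(object, fs, idx = NULL, ...) {
  idx <- idx %||% seq_along(object$stratum_key)
  scores <- setNames(rep(NA_real_, length(idx)), fs$sample_ids[idx])
  for (lev in names(object$pipes)) {
    s_idx <- idx[object$stratum_key[idx] == lev]
    if (length(s_idx) == 0L) next
    sub <- subset_feature_set(fs, s_idx)
    # any train statistic of the construction (qPCR-load fill) comes from
    # the fitted pipe, never from the rows being scored
    X <- materialize_features(sub, fills = object$pipes[[lev]]$fills)
    scores[fs$sample_ids[s_idx]] <- pipe_predict(object$pipes[[lev]], X, object$learner)
  }
  scores
}

#' Select hyperparameters on the inner folds
#'
#' Every candidate is evaluated on all inner folds x inner repeats of the
#' training set; candidates are ranked by mean inner R-squared (coefficient
#' of determination of the predicted probability against the 0/1 outcome),
#' and among the top five the one with the best mean inner auROC wins, ties
#' broken by draw order.
#'
#' @param fs feature set.
#' @param metadata cohort metadata.
#' @param train_idx outer-fold training rows.
#' @param candidates tibble from [sample_hyperparameters()].
#' @param blocks blocking key for inner stratification (from the fold
#'   plan).
#' @param n_inner_folds,n_inner_repeats inner geometry.
#' @param learner learner object.
#' @param composite race-composite switch.
#' @param seed seed; inner splits and learner seeds flow from substreams.
#' @param tag character tag making inner substreams unique per outer cell.
#' @return A list: `hp` (winning row as list), `candidate` (index),
#'   `table` (per-candidate mean R-squared and auROC).
#' @export
tune_nested <- function(fs, metadata, train_idx, candidates, blocks,
                        n_inner_folds = 5L, n_inner_repeats = 5L,
                        learner = xgb_learner(), composite = TRUE,
                        seed = 1L, tag = "") {
  y <- as.integer(metadata$outcome == "sPTB")
  key <- binary_stratum_key(metadata, composite)
  n_cand <- nrow(candidates)
  if (n_cand < 1L) abort_vagmet("no hyperparameter candidates supplied")
  cells <- list()
  for (irep in seq_len(n_inner_repeats)) {
    f <- assign_folds(blocks[train_idx], n_inner_folds,
                      substream_seed(seed, sprintf("inner_%s_%d", tag, irep)))
    for (ifold in seq_len(n_inner_folds)) {
      tr <- train_idx[f != ifold]
      te <- train_idx[f == ifold]
      ctxs <- list()
      for (lev in sort(unique(key))) {
        s_idx <- which(key == lev)
        s_tr <- intersect(tr, s_idx)
        s_te <- intersect(te, s_idx)
        if (length(s_te) == 0L || length(unique(y[s_tr])) < 2L) next
        ctxs[[lev]] <- make_fold_ctx(subset_feature_set(fs, s_idx), y[s_idx],
                                     match(s_tr, s_idx), match(s_te, s_idx))
      }
      cells[[length(cells) + 1L]] <- list(ctxs = ctxs, test = te)
    }
  }
  hp_rows <- lapply(seq_len(n_cand), function(i) {
    as.list(candidates[i, setdiff(names(candidates), "candidate")])
  })
  m_auc <- matrix(NA_real_, n_cand, length(cells))
  m_r2 <- matrix(NA_real_, n_cand, length(cells))
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    for (k in seq_len(n_cand)) {
      preds <- numeric(0)
      labs <- integer(0)
      ok <- TRUE
      for (lev in names(cell$ctxs)) {
        ctx <- cell$ctxs[[lev]]
        p <- tryCatch(
          eval_candidate(ctx, hp_rows[[k]], learner,
                         substream_seed(seed, sprintf("lrn_%s_%d_%s", tag, k, lev))),
          error = function(e) NULL
        )
        if (is.null(p)) {
          ok <- FALSE
          break
        }
        preds <- c(preds, p)
        labs <- c(labs, ctx$y[ctx$test_idx])
      }
      if (!ok || length(unique(labs)) < 2L) next
      m_auc[k, ci] <- auroc(preds, labs)
      m_r2[k, ci] <- r_squared(preds, labs)
    }
  }
  mean_auc <- rowMeans(m_auc, na.rm = TRUE)
  mean_r2 <- rowMeans(m_r2, na.rm = TRUE)
  best <- select_best_candidate(mean_r2, mean_auc)
  list(
    hp = hp_rows[[best]],
    candidate = best,
    table = tibble(candidate = seq_len(n_cand),
                   mean_r2 = mean_r2, mean_auroc = mean_auc)
  )
}

#' The hyperparameter selection rule
#'
#' Rank candidates by mean inner R-squared; among the top five, pick the
#' one with the best mean inner auROC, breaking ties by draw order. A
#' candidate outside the R-squared top five is never selected, whatever its
#' auROC.
#'
#' @param mean_r2,mean_auc per-candidate mean inner-fold metrics (`NaN`
#'   marks a degenerate candidate).
#' @return The index of the winning candidate.
#' @export
select_best_candidate <- function(mean_r2, mean_auc) {
  viable <- is.finite(mean_auc) & is.finite(mean_r2)
  if (!any(viable)) abort_vagmet("no viable hyperparameter candidate (all fits degenerate)")
  n_cand <- length(mean_r2)
  ord <- order(-mean_r2, seq_len(n_cand)) # draw order breaks ties
  top5 <- head(ord[viable[ord]], 5L)
  top5[order(-mean_auc[top5], top5)][1L]
}

#' Nested cross-validation of an sPTB classifier
#'
#' The full evaluation loop: for every outer (repeat, fold) cell,
#' hyperparameters are tuned on the inner folds of the training set alone
#' ([tune_nested()]), one composite model is fitted on the whole outer
#' training set with the winning candidate, and the held-out test fold is
#' scored exactly once. Out-of-fold scores are pooled per repeat; no
#' statistic of any test sample enters any fitted component.
#'
#' @param fs feature set from [build_feature_set()].
#' @param metadata cohort metadata.
#' @param candidates hyperparameter candidates ([sample_hyperparameters()]).
#' @param plan optional [build_fold_plan()]; built from `seed` when absent.
#' @param learner learner object.
#' @param composite race-composite switch (clinical models use `FALSE`).
#' @param seed master seed for folds, inner splits and learner seeds.
#' @return A `prediction_report`: out-of-fold `scores` (samples x repeats),
#'   labels, per-repeat and mean auROC/auPR, ROC points of repeat 1, and
#'   the selected hyperparameters per outer cell.
#' @export
nested_cv <- function(fs, metadata, candidates, plan = NULL,
                      learner = xgb_learner(), composite = TRUE, seed = 1L) {
  metadata <- cohort_metadata(metadata)
  plan <- plan %||% build_fold_plan(metadata, stratify_race = composite, seed = seed)
  y <- as.integer(metadata$outcome == "sPTB")
  n <- nrow(metadata)
  R <- plan$n_outer_repeats
  K <- plan$n_outer_folds
  scores <- matrix(NA_real_, n, R, dimnames = list(metadata$sample_id, NULL))
  selected <- list()
  for (r in seq_len(R)) {
    for (k in seq_len(K)) {
      test_idx <- which(plan$outer[, r] == k)
      train_idx <- which(plan$outer[, r] != k)
      tag <- sprintf("%d_%d", r, k)
      tn <- tune_nested(fs, metadata, train_idx, candidates, plan$strata,
                        n_inner_folds = plan$n_inner_folds,
                        n_inner_repeats = plan$n_inner_repeats,
                        learner = learner, composite = composite,
                        seed = seed, tag = tag)
      model <- fit_composite(fs, metadata, tn$hp, learner = learner,
                             train_idx = train_idx, composite = composite,
                             seed = substream_seed(seed, paste0("outer_fit_", tag)))
      scores[test_idx, r] <- predict(model, fs, idx = test_idx)
      selected[[length(selected) + 1L]] <- c(
        list(repeat_i = r, fold_i = k, candidate = tn$candidate),
        tn$hp
      )
    }
  }
  auc_rep <- apply(scores, 2L, auroc, labels = y)
  pr_rep <- apply(scores, 2L, aupr, labels = y)
  structure(list(
    scores = scores, labels = y, outcome_def = "sPTB",
    sample_ids = metadata$sample_id,
    auroc_per_repeat = auc_rep, auroc = mean(auc_rep),
    aupr_per_repeat = pr_rep, aupr = mean(pr_rep),
    roc = roc_points(scores[, 1L], y),
    selected = bind_rows(lapply(selected, as_tibble)),
    plan = plan, learner_name = learner$name, seed = seed
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "<prediction_report> outcome %s: auROC %.3f (per-repeat %s), auPR %.3f\n",
    x$outcome_def, x$auroc,
    paste(sprintf("%.3f", x$auroc_per_repeat), collapse = "/"), x$aupr
  ))
  invisible(x)
}

#' Re-evaluate out-of-fold scores against a stricter outcome definition
#'
#' Reclassification changes only the ground-truth labels (e.g. delivery
#' before 32 or 28 weeks); the score vectors are reused byte-identically,
#' with no retraining or rescoring.
#'
#' @param report a `prediction_report`.
#' @param metadata cohort metadata (for `gab_weeks`).
#' @param outcome_def `"sPTB"`, `"GAB<32"` or `"GAB<28"`.
#' @return A new `prediction_report` with updated labels and metrics.
#' @export
reclassify_outcome <- function(report, metadata, outcome_def = c("sPTB", "GAB<32", "GAB<28")) {
  outcome_def <- match.arg(outcome_def)
  metadata <- cohort_metadata(metadata)
  stopifnot(identical(report$sample_ids, metadata$sample_id))
  y <- switch(outcome_def,
    "sPTB" = as.integer(metadata$outcome == "sPTB"),
    "GAB<32" = as.integer(metadata$gab_weeks < 32),
    "GAB<28" = as.integer(metadata$gab_weeks < 28)
  )
  if (length(unique(y)) < 2L) abort_vagmet("reclassified outcome has a single class")
  out <- report
  out$labels <- y
  out$outcome_def <- outcome_def
  out$auroc_per_repeat <- apply(report$scores, 2L, auroc, labels = y)
  out$auroc <- mean(out$auroc_per_repeat)
  out$aupr_per_repeat <- apply(report$scores, 2L, aupr, labels = y)
  out$aupr <- mean(out$aupr_per_repeat)
  out$roc <- roc_points(report$scores[, 1L], y)
  out
}

# Hanley-McNeil standard error of an auROC estimate.
hanley_mcneil_se <- function(a, n_pos, n_neg) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
         (n_pos * n_neg))
}

#' Compare two classifiers' auROCs on the same samples
#'
#' `z = (auROC_a - auROC_b) / sqrt(SE_a^2 + SE_b^2)` with Hanley-McNeil
#' standard errors, two-sided normal p.
#'
#' @param scores_a,scores_b score vectors over the same samples.
#' @param labels shared binary labels.
#' @return A list: `auroc_a`, `auroc_b`, `z`, `p`.
#' @export
compare_auroc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    abort_vagmet("score vectors and labels must cover the same samples")
  }
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) abort_vagmet("labels must contain both classes")
  a <- auroc(scores_a, y)
  b <- auroc(scores_b, y)
  z <- (a - b) / sqrt(hanley_mcneil_se(a, n1, n0)^2 + hanley_mcneil_se(b, n1, n0)^2)
  list(auroc_a = a, auroc_b = b, z = z, p = 2 * pnorm(-abs(z)))
}

#' Refit on the full cohort and pick the best training-fit model
#'
#' Each hyperparameter set selected on an outer cell is refitted on the
#' entire cohort; the candidate with the best auROC on the same (training)
#' data is returned. That selection metric is a training fit, not a
#' generalization estimate, and the result is flagged accordingly.
#'
#' @param fs feature set.
#' @param metadata cohort metadata.
#' @param selected tibble of hyperparameter rows (e.g.
#'   `report$selected`).
#' @param learner learner object.
#' @param composite race-composite switch.
#' @param seed seed for the refits.
#' @return A list: `model` (`composite_predictor`), `selection`
#'   (per-candidate training auROC), `metric = "training_fit"`.
#' @export
select_final_model <- function(fs, metadata, selected, learner = xgb_learner(),
                               composite = TRUE, seed = 1L) {
  if (nrow(selected) == 0L) abort_vagmet("empty candidate list")
  metadata <- cohort_metadata(metadata)
  y <- as.integer(metadata$outcome == "sPTB")
  hp_cols <- setdiff(names(selected), c("repeat_i", "fold_i", "candidate"))
  fits <- vector("list", nrow(selected))
  train_auc <- numeric(nrow(selected))
  for (i in seq_len(nrow(selected))) {
    hp <- as.list(selected[i, hp_cols])
    fits[[i]] <- fit_composite(fs, metadata, hp, learner = learner,
                               composite = composite,
                               seed = substream_seed(seed, "final_fit", i))
    train_auc[i] <- auroc(predict(fits[[i]], fs), y)
  }
  best <- which.max(train_auc) # first maximum wins
  list(
    model = fits[[best]],
    selection = mutate(selected, training_auroc = train_auc),
    best = best,
    metric = "training_fit"
  )
}

#' Apply a fitted predictor to an external metabolome cohort
#'
#' Maps external features onto the training universe by identifier,
#' standardizes external values with the training statistics, fills
#' unmeasured features with the training post-standardization median, and
#' scores without any retraining or adaptation. Inference is deterministic.
#'
#' @param predictor a `composite_predictor` (typically a final model).
#' @param mat external raw [metab_matrix()].
#' @param stratum which stratum's model to apply (required when the
#'   predictor has several; external cohorts usually lack subject-level
#'   race).
#' @return A list: `scores` (named), `overlap_fraction`, `stratum`.
#' @export
apply_external <- function(predictor, mat, stratum = NULL) {
  stopifnot(inherits(predictor, "composite_predictor"), inherits(mat, "metab_matrix"))
  if (is.null(stratum)) {
    if (length(predictor$pipes) != 1L) {
      abort_vagmet("predictor has several strata; name the one to apply")
    }
    stratum <- names(predictor$pipes)[1L]
  }
  pipe <- predictor$pipes[[stratum]]
  if (is.null(pipe)) abort_vagmet(sprintf("unknown stratum: %s", stratum))
  v <- if (mat$scale_tag == "raw") log10(mat$values) else mat$values
  universe <- pipe$universe
  overlap <- intersect(colnames(v), universe)
  if (length(overlap) == 0L) abort_vagmet("no overlap with the predictor's feature universe")
  X <- matrix(NA_real_, nrow(v), length(universe),
              dimnames = list(rownames(v), universe))
  X[, overlap] <- v[, overlap]
  absent <- setdiff(universe, overlap)
  scores <- pipe_predict(pipe, X, predictor$learner, absent_cols = absent)
  list(
    scores = setNames(scores, rownames(v)),
    overlap_fraction = length(overlap) / length(universe),
    stratum = stratum
  )
}

#' Per-sample additive feature attributions (TreeSHAP)
#'
#' Delegates to the tree ensemble's native Shapley-value computation; the
#' per-sample contributions plus the baseline reproduce the model's margin
#' output exactly (additivity).
#'
#' @param predictor a `composite_predictor` fitted with the tree learner.
#' @param fs the feature set to attribute.
#' @param stratum stratum whose model (and samples) to explain.
#' @return A list: `contributions` (samples x model features), `baseline`,
#'   `margin` (model output on the attribution scale), and `ranking`
#'   (features by mean absolute contribution).
#' @export
attribute_features <- function(predictor, fs, stratum = NULL) {
  stopifnot(inherits(predictor, "composite_predictor"))
  if (predictor$learner$name != "xgboost") {
    abort_vagmet("feature attribution requires the tree-ensemble learner")
  }
  if (is.null(stratum)) stratum <- names(predictor$pipes)[1L]
  pipe <- predictor$pipes[[stratum]]
  s_idx <- which(predictor$stratum_key == stratum)
  sub <- subset_feature_set(fs, s_idx)
  X <- materialize_features(sub, fills = pipe$fills)
  M <- pipe_transform(pipe, X)
  d <- xgboost::xgb.DMatrix(M, nthread = 1)
  contrib <- predict(pipe$fit$model, d, predcontrib = TRUE)
  bias_col <- ncol(contrib) # the trailing intercept/baseline column
  baseline <- contrib[, bias_col]
  contrib <- contrib[, -bias_col, drop = FALSE]
  rownames(contrib) <- fs$sample_ids[s_idx]
  margin <- as.numeric(predict(pipe$fit$model, d, outputmargin = TRUE))
  ranking <- tibble(
    feature = colnames(contrib),
    mean_abs_contribution = colMeans(abs(contrib))
  ) |> arrange(desc(.data$mean_abs_contribution))
  list(contributions = contrib, baseline = baseline, margin = margin,
       ranking = ranking)
}
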