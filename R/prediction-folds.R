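#' Block-stratified cross-validation fold plan
#'
#' Builds the outer-fold assignments for repeated k-fold cross-validation,
#' block-stratified for deciles of gestational age at birth and (for
#' microbiome/metabolome/combined models) for the binary race grouping.
#' Deciles are computed on the full cohort; within each joint stratum,
#' samples are shuffled under a seeded substream and dealt round-robin
#' across folds, so every fold receives a balanced slice of each stratum up
#' to rounding. Repeats draw independent substreams of the same master
#' seed.
#'
#' @param metadata a [cohort_metadata()] tibble.
#' @param n_outer_folds,n_outer_repeats outer cross-validation geometry.
#' @param n_inner_folds,n_inner_repeats inner (tuning) geometry, recorded in
#'   the plan and used by [nested_cv()].
#' @param stratify_race also balance the `{Black, non-Black}` grouping.
#' @param seed master seed.
#' @return A `fold_plan`: `outer` (samples x repeats matrix of fold ids),
#'   `strata` (the blocking key), plus the geometry and seed.
#' @export
build_fold_plan <- function(metadata, n_outer_folds = 10L, n_outer_repeats = 5L,
                            n_inner_folds = 5L, n_inner_repeats = 5L,
                            stratify_race = TRUE, seed = 1L) {
  metadata <- cohort_metadata(metadata)
  n <- nrow(metadata)
  if (n_outer_folds > n) abort_vagmet("more folds than samples")
  gab_decile <- ceiling(rank(metadata$gab_weeks, ties.method = "first") / n * 10)
  strata <- as.character(gab_decile)
  if (stratify_race) {
    strata <- paste(strata, ifelse(metadata$race == "Black", "Black", "nonBlack"),
                    sep = "|")
  }
  outer <- matrix(NA_integer_, nrow = n, ncol = n_outer_repeats,
                  dimnames = list(metadata$sample_id, NULL))
  for (r in seq_len(n_outer_repeats)) {
    outer[, r] <- assign_folds(strata, n_outer_folds,
                               substream_seed(seed, "outer_folds", r))
  }
  structure(list(
    outer = outer, strata = strata,
    n_outer_folds = as.integer(n_outer_folds),
    n_outer_repeats = as.integer(n_outer_repeats),
    n_inner_folds = as.integer(n_inner_folds),
    n_inner_repeats = as.integer(n_inner_repeats),
    seed = as.integer(seed)
  ), class = "fold_plan")
}

# Deal shuffled stratum members round-robin across k folds, with a rotating
# stratum offset so small strata do not all land in fold 1.
assign_folds <- function(strata, k, seed) {
  n <- length(strata)
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d samples, %dx%d outer, %dx%d inner, seed %d\n",
              nrow(x$outer), x$n_outer_folds, x$n_outer_repeats,
              x$n_inner_folds, x$n_inner_repeats, x$seed))
  invisible(x)
}

#' Test-set sample ids of one (repeat, fold) cell of a plan
#'
#' @param plan a `fold_plan`.
#' @param repeat_i,fold_i indices.
#' @return Character vector of sample ids.
#' @export
fold_test_ids <- function(plan, repeat_i, fold_i) {
  rownames(plan$outer)[plan$outer[, repeat_i] == fold_i]
}

#' Draw hyperparameter candidates from the declared search space
#'
#' @param n number of independent draws.
#' @param seed integer seed; the same seed reproduces the same draws.
#' @param space a space description as produced by [default_hp_space()].
#' @return A tibble of candidate rows (one list-free column per
#'   hyperparameter), with the draw order preserved for tie-breaking.
#' @export
sample_hyperparameters <- function(n = 1000L, seed = 1L, space = default_hp_space()) {
  if (length(space) == 0L) abort_vagmet("empty hyperparameter space")
  draws <- with_seed(substream_seed(seed, "hp_draws"), {
    lapply(seq_len(n), function(i) {
      hp <- list()
      for (nm in names(space)) {
        d <- space[[nm]]
        hp[[nm]] <- switch(d$kind,
          choice = d$values[[sample.int(length(d$values), 1L, prob = d$prob)]],
          loguniform = exp(runif(1L, log(d$min), log(d$max))),
          int_loguniform = as.integer(round(exp(runif(1L, log(d$min), log(d$max))))),
          uniform = runif(1L, d$min, d$max),
          abort_vagmet(sprintf("unknown distribution kind: %s", d$kind))
        )
      }
      # a candidate applies either a PCA transform or a selection step
      if (!is.null(hp$transform) && hp$transform == "pca") {
        hp$select_method <- "none"
        hp$impute <- TRUE # PCA needs a complete matrix
      } else {
        hp$pca_k <- 0L
      }
      hp
    })
  })
  out <- bind_rows(lapply(draws, as_tibble))
  out$candidate <- seq_len(n)
  out
}

#' Default desk-scale hyperparameter search space
#'
#' Feature-pipeline switches (robust standardization, detection-limit
#' imputation, optional PCA, feature selection by rank correlation,
#' information gain, sparsity or tree importance) and boosted-tree learner
#' parameters. Ranges are deliberately modest: shallow trees and few
#' boosting rounds fit the small-cohort, strong-regularization regime.
#'
#' @return A named list of distribution descriptions.
#' @export
default_hp_space <- function() {
  list(
    standardize = list(kind = "choice", values = list(TRUE, FALSE), prob = c(0.8, 0.2)),
    impute = list(kind = "choice", values = list(TRUE, FALSE), prob = c(0.7, 0.3)),
    transform = list(kind = "choice", values = list("none", "pca"), prob = c(0.8, 0.2)),
    pca_k = list(kind = "choice", values = list(5L, 10L, 20L), prob = NULL),
    select_method = list(kind = "choice",
                         values = list("rankcorr", "infogain", "sparsity", "importance"),
                         prob = NULL),
    select_m = list(kind = "choice", values = list(10L, 20L, 40L, 80L), prob = NULL),
    max_depth = list(kind = "choice", values = list(2L, 3L), prob = NULL),
    eta = list(kind = "loguniform", min = 0.08, max = 0.6),
    nrounds = list(kind = "int_loguniform", min = 6, max = 24),
    subsample = list(kind = "uniform", min = 0.6, max = 1),
    colsample = list(kind = "uniform", min = 0.5, max = 1),
    min_child_weight = list(kind = "choice", values = list(1, 3, 5), prob = NULL),
    lambda = list(kind = "loguniform", min = 0.5, max = 8)
  )
}
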