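# Feature sets and the per-fold feature pipeline.
#
# A feature_set describes how raw cohort objects turn into a numeric
# feature matrix; any statistic the construction needs (the qPCR-load
# training mean, standardization centers/scales, imputation minima, PCA
# rotations, selection scores) is computed from training rows only, so
# train-test sterility is structural rather than disciplinary.

#' Assemble a feature set for the sPTB classifiers
#'
#' @param type `"clinical"` (age, BMI, parity, PTB history, race),
#'   `"metabolome"` (log10 metabolite levels, missing values retained),
#'   `"microbiome"` (absolute abundances; samples lacking qPCR load get the
#'   training-mean load at materialization), or `"combined"`.
#' @param metadata a [cohort_metadata()] tibble.
#' @param mat raw [metab_matrix()] (metabolome/combined).
#' @param taxa [taxa_table()] (microbiome/combined).
#' @return A `feature_set` object.
#' @export
build_feature_set <- function(type = c("clinical", "metabolome", "microbiome", "combined"),
                              metadata, mat = NULL, taxa = NULL) {
  type <- match.arg(type)
  metadata <- cohort_metadata(metadata)
  ids <- metadata$sample_id
  part <- function(t) build_feature_set(t, metadata, mat = mat, taxa = taxa)
  fs <- switch(type,
    clinical = {
      X <- cbind(
        age_years = as.numeric(metadata$age_years %||% rep(NA_real_, length(ids))),
        bmi = as.numeric(metadata$bmi),
        nulliparous = as.numeric(metadata$nulliparous),
        ptb_history = as.numeric(metadata$ptb_history),
        race_black = as.numeric(metadata$race == "Black"),
        race_white = as.numeric(metadata$race == "White")
      )
      rownames(X) <- ids
      list(type = type, X = X)
    },
    metabolome = {
      if (is.null(mat)) abort_vagmet("metabolome features need a metabolite matrix")
      v <- if (mat$scale_tag == "raw") log10(mat$values) else mat$values
      list(type = type, X = v[ids, , drop = FALSE])
    },
    microbiome = {
      if (is.null(taxa)) abort_vagmet("microbiome features need a taxa table")
      list(type = type,
           rel = taxa$rel_abundance[ids, , drop = FALSE],
           load = taxa$total_load[ids])
    },
    combined = {
      list(type = type,
           parts = list(part("clinical"), part("metabolome"), part("microbiome")))
    }
  )
  fs$sample_ids <- ids
  class(fs) <- "feature_set"
  fs
}

# Materialize the full feature matrix. `train_idx` rows supply any
# statistic the construction needs (currently only the mean qPCR load);
# alternatively a previously stored `fills` list reapplies the training
# statistic to new rows. The fills used are attached as an attribute.
materialize_features <- function(fs, train_idx = NULL, fills = NULL) {
  out <- switch(fs$type,
    clinical = fs$X,
    metabolome = fs$X,
    microbiome = {
      fill <- fills$load_fill %||% mean(fs$load[train_idx], na.rm = TRUE)
      if (!is.finite(fill)) fill <- 0
      loadv <- ifelse(is.na(fs$load), fill, fs$load)
      X <- log10(sweep(fs$rel, 1L, loadv, "*") + 1)
      colnames(X) <- paste0("abs_", colnames(fs$rel))
      attr(X, "load_fill") <- fill
      X
    },
    combined = {
      parts <- lapply(seq_along(fs$parts), function(i) {
        materialize_features(fs$parts[[i]], train_idx = train_idx,
                             fills = fills$parts[[i]])
      })
      X <- do.call(cbind, parts)
      attr(X, "part_fills") <- lapply(parts, extract_fills)
      X
    }
  )
  out
}

extract_fills <- function(X) {
  list(load_fill = attr(X, "load_fill"), parts = attr(X, "part_fills"))
}

col_medians <- function(X) apply(X, 2L, median, na.rm = TRUE)

# median and trimmed SD per column from a single sorted pass
col_robust_stats <- function(X, trim = 0.05) {
  p <- ncol(X)
  med <- numeric(p)
  tsd <- numeric(p)
  for (j in seq_len(p)) {
    x <- sort.int(X[, j], method = "quick") # drops NA
    n <- length(x)
    if (n == 0L) {
      med[j] <- NA_real_
      tsd[j] <- 1
      next
    }
    half <- n %/% 2L
    med[j] <- if (n %% 2L == 1L) x[half + 1L] else (x[half] + x[half + 1L]) / 2
    if (n < 3L) {
      tsd[j] <- 1
      next
    }
    k <- ceiling(trim * n)
    s <- sd(x[seq.int(k + 1L, n - k)])
    tsd[j] <- if (!is.finite(s) || s == 0) 1 else s
  }
  list(median = med, trimmed_sd = tsd)
}

# Per-fold context: cached matrices and lazily cached selection scores and
# PCA rotations, all derived from training rows only.
make_fold_ctx <- function(fs, y, train_idx, test_idx = integer()) {
  X <- materialize_features(fs, train_idx)
  fills <- extract_fills(X)
  Xtr <- X[train_idx, , drop = FALSE]
  stats <- col_robust_stats(Xtr)
  center <- stats$median
  scale_ <- stats$trimmed_sd
  center[is.na(center)] <- 0
  X_std <- sweep(sweep(X, 2L, center, "-"), 2L, scale_, "/")
  impute_mins <- function(M) {
    mins <- apply(M[train_idx, , drop = FALSE], 2L, function(x) {
      if (all(is.na(x))) 0 else min(x, na.rm = TRUE)
    })
    out <- M
    for (j in seq_len(ncol(M))) {
      nas <- is.na(out[, j])
      if (any(nas)) out[nas, j] <- mins[j]
    }
    list(M = out, mins = mins)
  }
  ir <- impute_mins(X)
  is_ <- impute_mins(X_std)
  env <- new.env(parent = emptyenv())
  ctx <- list(
    y = y, train_idx = train_idx, test_idx = test_idx,
    X_raw = X, X_std = X_std,
    Xi_raw = ir$M, Xi_std = is_$M,
    mins_raw = ir$mins, mins_std = is_$mins,
    center = center, scale = scale_,
    median_post_raw = center, # the training median on the raw basis
    fills = fills,
    cache = env
  )
  ctx
}

# Selection scores on the standardized, imputed training matrix (a fixed,
# train-only scoring basis shared by all candidates).
ctx_scores <- function(ctx, method, learner_seed = 0L) {
  key <- paste0("score_", method)
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  Xtr <- ctx$Xi_std[ctx$train_idx, , drop = FALSE]
  ytr <- ctx$y[ctx$train_idx]
  s <- switch(method,
    rankcorr = {
      r <- suppressWarnings(abs(cor(Xtr, ytr, method = "spearman")))
      r[is.na(r)] <- 0
      drop(r)
    },
    sparsity = colMeans(!is.na(ctx$X_raw[ctx$train_idx, , drop = FALSE])),
    infogain = {
      # vectorised information gain of the median split of each feature
      med <- col_medians(Xtr)
      b <- sweep(Xtr, 2L, med, ">")
      n <- length(ytr)
      n1 <- colSums(b)                 # above the median
      n11 <- colSums(b & (ytr == 1L))  # above and case
      k1 <- sum(ytr == 1L)
      ent2 <- function(a, tot) {
        # entropy (bits) of a binary split with `a` of `tot` in one class
        p <- a / pmax(tot, 1)
        q <- 1 - p
        h <- numeric(length(p))
        ok <- p > 0 & p < 1
        h[ok] <- -(p[ok] * log2(p[ok]) + q[ok] * log2(q[ok]))
        h
      }
      h0 <- ent2(k1, n)
      hc <- (n1 / n) * ent2(n11, n1) + ((n - n1) / n) * ent2(k1 - n11, n - n1)
      as.numeric(h0 - hc)
    },
    importance = {
      fit <- xgb_learner()$fit(Xtr, ytr,
                               list(max_depth = 3L, eta = 0.3, nrounds = 30L),
                               seed = learner_seed)
      imp <- xgboost::xgb.importance(model = fit$model)
      s <- setNames(rep(0, ncol(Xtr)), colnames(Xtr))
      s[imp$Feature] <- imp$Gain
      s
    },
    abort_vagmet(sprintf("unknown selection method: %s", method))
  )
  ctx$cache[[key]] <- s
  s
}

ctx_pca <- function(ctx, standardize, k_max = 20L) {
  key <- paste0("pca_", standardize)
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  M <- if (standardize) ctx$Xi_std else ctx$Xi_raw
  pc <- prcomp(M[ctx$train_idx, , drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = min(k_max, length(ctx$train_idx) - 1L, ncol(M)))
  proj <- sweep(M, 2L, pc$center, "-") %*% pc$rotation
  out <- list(center = pc$center, rotation = pc$rotation, proj = proj)
  ctx$cache[[key]] <- out
  out
}

# The model-input matrix (all cohort rows) for one candidate.
candidate_matrix <- function(ctx, hp, learner_seed = 0L) {
  standardize <- isTRUE(hp$standardize)
  impute <- isTRUE(hp$impute) || (hp$pca_k %||% 0L) > 0L
  if ((hp$pca_k %||% 0L) > 0L) {
    pca <- ctx_pca(ctx, standardize)
    k <- min(hp$pca_k, ncol(pca$proj))
    return(pca$proj[, seq_len(k), drop = FALSE])
  }
  M <- if (standardize) {
    if (impute) ctx$Xi_std else ctx$X_std
  } else {
    if (impute) ctx$Xi_raw else ctx$X_raw
  }
  method <- hp$select_method %||% "none"
  if (method != "none" && (hp$select_m %||% 0L) < ncol(M)) {
    s <- ctx_scores(ctx, method, learner_seed)
    keep <- order(s, decreasing = TRUE)[seq_len(hp$select_m)]
    M <- M[, sort(keep), drop = FALSE]
  }
  M
}

# Fit a candidate on the context's training rows; returns test-row scores.
eval_candidate <- function(ctx, hp, learner, seed) {
  M <- candidate_matrix(ctx, hp, learner_seed = seed)
  fit <- learner$fit(M[ctx$train_idx, , drop = FALSE], ctx$y[ctx$train_idx],
                     hp, seed)
  learner$predict(fit, M[ctx$test_idx, , drop = FALSE])
}

# Fit a candidate and keep everything needed to score new data later.
fit_pipe <- function(ctx, hp, learner, seed) {
  M <- candidate_matrix(ctx, hp, learner_seed = seed)
  fit <- learner$fit(M[ctx$train_idx, , drop = FALSE], ctx$y[ctx$train_idx],
                     hp, seed)
  standardize <- isTRUE(hp$standardize)
  impute <- isTRUE(hp$impute) || (hp$pca_k %||% 0L) > 0L
  pca <- if ((hp$pca_k %||% 0L) > 0L) {
    p <- ctx_pca(ctx, standardize)
    k <- min(hp$pca_k, ncol(p$rotation))
    list(center = p$center, rotation = p$rotation[, seq_len(k), drop = FALSE])
  }
  structure(list(
    hp = hp, learner_name = learner$name, fit = fit, seed = seed,
    universe = colnames(ctx$X_raw),
    fills = ctx$fills,
    standardize = standardize, impute = impute,
    center = ctx$center, scale = ctx$scale,
    mins = if (standardize) ctx$mins_std else ctx$mins_raw,
    median_post = if (standardize) rep(0, ncol(ctx$X_raw)) else ctx$median_post_raw,
    pca = pca,
    selected = colnames(M)
  ), class = "vm_pipe")
}

# Transform a raw feature matrix (columns = pipe universe; NA columns allowed
# for unmeasured features, filled with the training post-standardization
# median) into the model-input space of a fitted pipe.
pipe_transform <- function(pipe, X, absent_cols = character()) {
  stopifnot(identical(colnames(X), pipe$universe))
  if (pipe$standardize) {
    X <- sweep(sweep(X, 2L, pipe$center, "-"), 2L, pipe$scale, "/")
  }
  if (length(absent_cols) > 0L) {
    j <- match(absent_cols, pipe$universe)
    X[, j] <- matrix(pipe$median_post[j], nrow = nrow(X), ncol = length(j),
                     byrow = TRUE)
  }
  if (pipe$impute) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- pipe$mins[j]
    }
  }
  if (!is.null(pipe$pca)) {
    return(sweep(X, 2L, pipe$pca$center, "-") %*% pipe$pca$rotation)
  }
  X[, pipe$selected, drop = FALSE]
}

pipe_predict <- function(pipe, X, learner, absent_cols = character()) {
  learner$predict(pipe$fit, pipe_transform(pipe, X, absent_cols))
}
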