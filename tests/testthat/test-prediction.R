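test_that("fold plan: partition per repeat, balance, determinism", {
  ch <- small_cohort()
  plan <- build_fold_plan(ch$metadata, n_outer_folds = 5, n_outer_repeats = 3,
                          seed = 4)
  n <- nrow(ch$metadata)
  for (r in 1:3) {
    expect_setequal(unlist(lapply(1:5, fold_test_ids, plan = plan, repeat_i = r)),
                    ch$metadata$sample_id)
  }
  # case/control ratio per fold within +-2 of the global split
  y <- ch$metadata$outcome == "sPTB"
  for (r in 1:3) for (k in 1:5) {
    in_fold <- plan$outer[, r] == k
    expect_lte(abs(sum(y[in_fold]) - sum(y) * mean(in_fold)), 2.5)
  }
  plan2 <- build_fold_plan(ch$metadata, n_outer_folds = 5, n_outer_repeats = 3,
                           seed = 4)
  expect_identical(plan$outer, plan2$outer)
  expect_error(build_fold_plan(ch$metadata, n_outer_folds = 1000), "more folds")
})

test_that("hyperparameter draws are reproducible and stay in the space", {
  cand <- sample_hyperparameters(200, seed = 8)
  cand2 <- sample_hyperparameters(200, seed = 8)
  expect_identical(cand, cand2)
  expect_true(all(cand$max_depth %in% 2:3))
  expect_true(all(cand$select_method %in% c("rankcorr", "infogain", "sparsity",
                                            "importance", "none")))
  expect_true(all(cand$eta >= 0.08 & cand$eta <= 0.6))
  expect_true(all(cand$nrounds >= 6 & cand$nrounds <= 24))
  expect_true(all(cand$pca_k[cand$transform == "none"] == 0))
  expect_true(all(cand$select_method[cand$transform == "pca"] == "none"))
  expect_error(sample_hyperparameters(1, space = list()), "empty")
})

test_that("auROC: worked example, tie convention, brute-force oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)

  brute <- function(s, y) {
    pos <- s[y == 1]
    neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(31, {
    for (i in 1:5) {
      y <- rbinom(40, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(40), 1) # coarse scores force ties
      expect_equal(auroc(s, y), brute(s, y))
    }
  })
})

test_that("auPR integrates precision over recall correctly on a worked case", {
  # scores descending: labels 1,0,1 -> precision 1, 1/2, 2/3; recall 1/2,1/2,1
  s <- c(0.9, 0.8, 0.7)
  y <- c(1, 0, 1)
  expect_equal(aupr(s, y), 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(aupr(c(0.9, 0.8), c(1, 0)), 1)
})

test_that("Hanley-McNeil SE matches the closed form at auROC = 0.5", {
  # A = .5, Q1 = Q2 = 1/3, n1 = n0 = 50
  se_expected <- sqrt((0.25 + 49 * (1 / 3 - 0.25) * 2) / 2500)
  expect_equal(vagmet:::hanley_mcneil_se(0.5, 50, 50), se_expected, tolerance = 1e-12)

  withr::with_seed(17, {
    y <- rep(c(1, 0), each = 25)
    s1 <- rnorm(50, y)
    s2 <- rnorm(50, 0.5 * y)
    same <- compare_auroc(s1, s1, y)
    expect_equal(same$z, 0)
    expect_equal(same$p, 1)
    ab <- compare_auroc(s1, s2, y)
    ba <- compare_auroc(s2, s1, y)
    expect_equal(ab$z, -ba$z)
    expect_equal(ab$p, ba$p)
  })
})

test_that("selection rule: R-squared gates the top five, auROC picks within", {
  r2 <- c(0.30, 0.29, 0.28, 0.27, 0.26, 0.10)
  auc <- c(0.60, 0.61, 0.62, 0.63, 0.64, 0.99)
  expect_equal(select_best_candidate(r2, auc), 5L) # rank 6 never wins
  expect_equal(select_best_candidate(0.5, 0.7), 1L)
  dom <- select_best_candidate(c(0.4, 0.2), c(0.9, 0.5))
  expect_equal(dom, 1L)
  # ties broken by draw order
  expect_equal(select_best_candidate(c(0.3, 0.3), c(0.7, 0.7)), 1L)
  expect_error(select_best_candidate(NaN, NaN), "viable")
})

test_that("composite scores pool per-stratum models exactly and stay isolated", {
  ch <- small_cohort()
  fs <- build_feature_set("metabolome", ch$metadata, mat = ch$matrix)
  hp <- list(standardize = TRUE, impute = TRUE, transform = "none", pca_k = 0L,
             select_method = "rankcorr", select_m = 15L)
  model <- fit_composite(fs, ch$metadata, hp, learner = stub_learner(),
                         composite = TRUE, seed = 2)
  pooled <- predict(model, fs)
  key <- ifelse(ch$metadata$race == "Black", "Black", "nonBlack")
  for (lev in unique(key)) {
    idx <- which(key == lev)
    expect_identical(pooled[idx], predict(model, fs, idx = idx))
  }

  # perturbing the other stratum's training data leaves this stratum alone
  md2 <- ch$metadata
  v2 <- ch$matrix$values
  nb <- which(key == "nonBlack")
  v2[nb, ] <- v2[nb, ] * 3
  fs2 <- build_feature_set("metabolome", md2, mat = metab_matrix(v2, "raw"))
  model2 <- fit_composite(fs2, md2, hp, learner = stub_learner(),
                          composite = TRUE, seed = 2)
  b <- which(key == "Black")
  expect_equal(predict(model2, fs2, idx = b), predict(model, fs, idx = b),
               tolerance = 1e-12)
})

test_that("single-stratum composite equals the plain pipeline", {
  ch <- small_cohort()
  fs <- build_feature_set("metabolome", ch$metadata, mat = ch$matrix)
  hp <- list(standardize = TRUE, impute = TRUE, transform = "none", pca_k = 0L,
             select_method = "none", select_m = 0L)
  m1 <- fit_composite(fs, ch$metadata, hp, learner = stub_learner(),
                      composite = FALSE, seed = 5)
  expect_length(m1$pipes, 1L)
  expect_named(m1$pipes, "all")
})

test_that("microbiome features impute missing qPCR load from training mean", {
  ch <- small_cohort()
  fs <- build_feature_set("microbiome", ch$metadata, taxa = ch$taxa)
  miss <- which(is.na(fs$load))
  train_idx <- setdiff(seq_len(nrow(ch$metadata)), miss)[1:40]
  X <- vagmet:::materialize_features(fs, train_idx)
  fill <- attr(X, "load_fill")
  expect_equal(fill, mean(fs$load[train_idx], na.rm = TRUE))
  expected_row <- log10(fs$rel[miss[1], ] * fill + 1)
  expect_equal(unname(X[miss[1], ]), unname(expected_row))
})

test_that("nested CV with the stub learner: sterility and report geometry", {
  ch <- small_cohort()
  fs <- build_feature_set("metabolome", ch$metadata, mat = ch$matrix)
  cand <- sample_hyperparameters(3, seed = 1)
  plan <- build_fold_plan(ch$metadata, n_outer_folds = 3, n_outer_repeats = 2,
                          n_inner_folds = 2, n_inner_repeats = 1, seed = 6)
  rep <- nested_cv(fs, ch$metadata, cand, plan = plan,
                   learner = stub_learner(), seed = 6)
  expect_false(anyNA(rep$scores))
  expect_equal(dim(rep$scores), c(nrow(ch$metadata), 2L))
  expect_equal(nrow(rep$selected), 6L)
  expect_true(all(rep$auroc_per_repeat >= 0 & rep$auroc_per_repeat <= 1))
  # determinism
  rep2 <- nested_cv(fs, ch$metadata, cand, plan = plan,
                    learner = stub_learner(), seed = 6)
  expect_identical(rep$scores, rep2$scores)
})

test_that("reclassified outcomes change labels only, never scores", {
  ch <- small_cohort()
  fs <- build_feature_set("clinical", ch$metadata)
  cand <- sample_hyperparameters(2, seed = 3)
  plan <- build_fold_plan(ch$metadata, n_outer_folds = 3, n_outer_repeats = 1,
                          n_inner_folds = 2, n_inner_repeats = 1,
                          stratify_race = FALSE, seed = 2)
  rep <- nested_cv(fs, ch$metadata, cand, plan = plan,
                   learner = stub_learner(), composite = FALSE, seed = 2)
  rc32 <- reclassify_outcome(rep, ch$metadata, "GAB<32")
  expect_identical(rc32$scores, rep$scores)
  expect_false(identical(rc32$labels, rep$labels))
  expect_identical(reclassify_outcome(rep, ch$metadata, "sPTB")$labels, rep$labels)
})

test_that("external application: identity on full overlap, diagnostics, determinism", {
  ch <- small_cohort()
  fs <- build_feature_set("metabolome", ch$metadata, mat = ch$matrix)
  hp <- list(standardize = TRUE, impute = TRUE, transform = "none", pca_k = 0L,
             select_method = "rankcorr", select_m = 10L)
  model <- fit_composite(fs, ch$metadata, hp, composite = TRUE, seed = 9)
  res <- apply_external(model, ch$matrix, stratum = "Black")
  expect_equal(res$overlap_fraction, 1)
  key <- ifelse(ch$metadata$race == "Black", "Black", "nonBlack")
  b <- which(key == "Black")
  internal <- predict(model, fs, idx = b)
  expect_equal(res$scores[names(internal)], internal, tolerance = 1e-9)

  sub <- metab_matrix(ch$matrix$values[, 1:20], "raw")
  res2 <- apply_external(model, sub, stratum = "Black")
  expect_equal(res2$overlap_fraction, 20 / ncol(ch$matrix$values))
  res3 <- apply_external(model, sub, stratum = "Black")
  expect_identical(res2$scores, res3$scores)
  none <- metab_matrix(matrix(1:4 + 0.1, 2, 2,
                              dimnames = list(c("a", "b"), c("zz1", "zz2"))), "raw")
  expect_error(apply_external(model, none, stratum = "Black"), "no overlap")
})

test_that("tree attributions are additive and concentrate on the used feature", {
  withr::with_seed(23, {
    n <- 80
    x1 <- rnorm(n)
    X <- cbind(signal = x1, noise = rnorm(n, sd = 1e-6))
    rownames(X) <- sprintf("s%03d", 1:n)
    y <- as.integer(x1 > 0)
    md <- tibble::tibble(
      sample_id = rownames(X), outcome = ifelse(y == 1, "sPTB", "TB"),
      gab_weeks = ifelse(y == 1, 30, 39), race = "Black",
      age_years = 30, bmi = 25, nulliparous = FALSE, ptb_history = FALSE,
      progesterone = FALSE, batch = "B1"
    )
    v <- 10^X
    colnames(v) <- colnames(X)
    fs <- build_feature_set("metabolome", md, mat = metab_matrix(v, "raw"))
    hp <- list(standardize = FALSE, impute = FALSE, transform = "none",
               pca_k = 0L, select_method = "none", select_m = 0L,
               max_depth = 2L, eta = 0.3, nrounds = 20L)
    model <- fit_composite(fs, md, hp, composite = TRUE, seed = 3)
    att <- attribute_features(model, fs, stratum = "Black")
    expect_lt(max(abs(rowSums(att$contributions) + att$baseline - att$margin)),
              1e-6)
    expect_identical(att$ranking$feature[1], "signal")
    expect_gt(att$ranking$mean_abs_contribution[1],
              100 * att$ranking$mean_abs_contribution[2])
  })
})

test_that("final-model selection refits on everything and flags training fit", {
  ch <- small_cohort()
  fs <- build_feature_set("metabolome", ch$metadata, mat = ch$matrix)
  selected <- tibble::tibble(
    repeat_i = 1:2, fold_i = 1:2, candidate = 1:2,
    standardize = TRUE, impute = TRUE, transform = "none", pca_k = 0L,
    select_method = "rankcorr", select_m = c(5L, 20L)
  )
  fin <- select_final_model(fs, ch$metadata, selected, learner = stub_learner(),
                            seed = 7)
  expect_identical(fin$metric, "training_fit")
  expect_equal(nrow(fin$selection), 2L)
  expect_s3_class(fin$model, "composite_predictor")
  expect_equal(fin$best, which.max(fin$selection$training_auroc))
  # identical candidates: the first is returned
  same <- select_final_model(fs, ch$metadata, selected[c(1, 1), ],
                             learner = stub_learner(), seed = 7)
  expect_equal(same$best, 1L)
  expect_error(select_final_model(fs, ch$metadata, selected[0, ]), "empty")
})
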