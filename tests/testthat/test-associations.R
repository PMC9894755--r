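test_that("BH q-values match the step-up oracle and grouped correction", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  p <- c(0.01, 0.5, 0.02, 0.6)
  g <- c("a", "a", "b", "b")
  q <- bh_fdr(p, g)
  expect_equal(q[1:2], p.adjust(p[1:2], "BH"))
  expect_equal(q[3:4], p.adjust(p[3:4], "BH"))
})

test_that("scan agrees with wilcox.test feature by feature", {
  ch <- small_cohort()
  res <- association_scan(ch$matrix, ch$metadata, strata = "all")
  case <- ch$metadata$outcome == "sPTB"
  for (f in sample(res$feature_id, 8)) {
    x <- ch$matrix$values[case, f]
    y <- ch$matrix$values[!case, f]
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    row <- res[res$feature_id == f, ]
    expect_equal(row$U, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(row$p, ref$p.value, tolerance = 1e-6)
  }
})

test_that("exact branch: {1,2,3} vs {4,5,6} matches the exact null", {
  v <- matrix(10^c(1, 2, 3, 4, 5, 6), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:6), "f"))
  md <- toy_metadata(6, n_case = 3)
  res <- association_scan(metab_matrix(v, "raw"), md, strata = "all")
  ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(res$p, ref$p.value) # 2/20
  expect_equal(res$U, 0)
  expect_equal(res$direction, -1)
})

test_that("exact and tie-corrected approximate branches agree closely", {
  withr::with_seed(21, {
    for (i in 1:20) {
      x <- rnorm(12)
      y <- rnorm(15, 0.5)
      pe <- wilcox.test(x, y, exact = TRUE)$p.value
      prep <- vagmet:::mw_prep(matrix(c(x, y), ncol = 1))
      pa <- vagmet:::mw_scan(prep, matrix(c(rep(1, 12), rep(0, 15)), ncol = 1))$p[1, 1]
      expect_lt(abs(pe - pa), 0.01)
    }
  })
})

test_that("swapping case/control flips direction and preserves p", {
  ch <- small_cohort()
  md <- ch$metadata
  res1 <- association_scan(ch$matrix, md, strata = "all")
  flipped <- md
  flipped$outcome <- ifelse(md$outcome == "sPTB", "TB", "sPTB")
  flipped$gab_weeks <- ifelse(flipped$outcome == "sPTB", 30, 39)
  res2 <- association_scan(ch$matrix, flipped, strata = "all")
  expect_equal(res1$p, res2$p, tolerance = 1e-9)
  expect_equal(res1$direction, -res2$direction)
})

test_that("prevalence filter excludes low-detection features with a record", {
  withr::with_seed(4, {
    v <- matrix(runif(40, 1, 10), 20, 2,
                dimnames = list(sprintf("s%02d", 1:20), c("common", "rare")))
    v[1:12, "rare"] <- NA # detected in 40% only
    md <- toy_metadata(20, n_case = 8)
    res <- association_scan(metab_matrix(v, "raw"), md, strata = "all",
                            min_prevalence = 0.5)
    expect_false("rare" %in% res$feature_id)
    exc <- attr(res, "excluded")
    expect_true("rare" %in% exc$feature_id)
    expect_match(exc$reason[exc$feature_id == "rare"], "detection fraction")
  })
})

test_that("scan is invariant to monotone per-feature transforms", {
  ch <- small_cohort()
  res1 <- association_scan(ch$matrix, ch$metadata, strata = "all")
  cubed <- metab_matrix(ch$matrix$values^3, "raw")
  res2 <- association_scan(cubed, ch$metadata, strata = "all")
  expect_equal(res1$U, res2$U)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("null cohort rejection rate is binomially consistent with alpha", {
  cfg <- sim_config(n_samples = 120L, n_cases = 40L, n_named = 280L,
                    n_unnamed = 20L, cluster_separation = 0, censor_frac = 0.3,
                    seed = 77L)
  ch <- generate_cohort(cfg)
  res <- association_scan(ch$matrix, ch$metadata, strata = "all")
  alpha <- 0.05
  rate <- mean(res$p < alpha)
  n <- nrow(res)
  expect_gte(n, 290)
  tol <- 3 * sqrt(alpha * (1 - alpha) / n)
  expect_lt(abs(rate - alpha), tol + 0.01)
})

test_that("stratified scans honour preconditions and skip undersized strata", {
  ch <- small_cohort()
  res <- association_scan(ch$matrix, ch$metadata,
                          strata = c("all", "Black", "White", "GAB<28_Black"))
  expect_true(all(c("all", "Black") %in% res$stratum))
  # single undersized stratum errors instead of silently skipping
  tiny <- toy_metadata(8, n_case = 2)
  v <- matrix(runif(16, 1, 2), 8, 2,
              dimnames = list(tiny$sample_id, c("f1", "f2")))
  expect_error(association_scan(metab_matrix(v, "raw"), tiny, strata = "all"),
               ">= 3 cases")
})

test_that("signed log-p ranking: direct formula, cancellation, order invariance", {
  rec <- tibble::tibble(
    feature_id = c("f1", "f2", "f2"),
    stratum = c("all", "all", "Black"),
    p = c(0.01, 0.001, 0.001),
    direction = c(1, 1, -1)
  )
  out <- rank_by_signed_logp(rec)
  expect_equal(out$score[out$feature_id == "f1"], 2)
  expect_equal(out$score[out$feature_id == "f2"], 0)
  expect_identical(out$feature_id[1], "f1")
  out2 <- rank_by_signed_logp(rec[c(3, 1, 2), ])
  expect_equal(out, out2)
})
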