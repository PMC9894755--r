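test_that("absolute abundance: scaling, conservation, exclusions, guards", {
  rel <- rbind(s1 = c(0.5, 0.5), s2 = c(0.25, 0.75), s3 = c(1, 0))
  colnames(rel) <- c("t1", "t2")
  tt <- taxa_table(rel, total_load = c(s1 = 1000, s2 = 2000))
  abs_m <- estimate_absolute_abundance(tt)
  expect_equal(unname(abs_m["s1", ]), c(500, 500))
  expect_equal(unname(rowSums(abs_m)), c(1000, 2000))
  expect_identical(attr(abs_m, "excluded_samples"), "s3")
})

test_that("pairing threshold arithmetic: ceil(0.22 * 232) = 52 excludes 40 pairs", {
  n <- 60
  withr::with_seed(2, {
    taxa <- matrix(runif(n * 2), n, 2, dimnames = list(sprintf("s%03d", 1:n),
                                                       c("t1", "t2")))
    v <- matrix(runif(n, 1, 5), n, 1, dimnames = list(rownames(taxa), "f1"))
    v[1:20, 1] <- NA # 40 complete pairs
  })
  mat <- metab_matrix(v, "raw")
  # fraction contract against the full-cohort denominator of 232
  res <- correlation_network(taxa, mat, min_pair_fraction = 0.22, n_cohort = 232)
  expect_equal(attr(res, "threshold"), 52L)
  expect_equal(nrow(res), 0L)
  expect_equal(nrow(attr(res, "uncomputed")), 2L)
  # the explicit integer threshold of 50 also excludes 40 pairs
  res2 <- correlation_network(taxa, mat, min_pairs = 50)
  expect_equal(nrow(res2), 0L)
  # at a threshold below 40 the pair is computed
  res3 <- correlation_network(taxa, mat, min_pairs = 30)
  expect_equal(nrow(res3), 2L)
})

test_that("constant vectors are recorded as uncomputed, not NA edges", {
  n <- 30
  taxa <- matrix(c(rep(1, n), seq_len(n)), n, 2,
                 dimnames = list(sprintf("s%02d", 1:n), c("flat", "vary")))
  v <- matrix(seq_len(n) + 0.5, n, 1, dimnames = list(rownames(taxa), "f1"))
  res <- correlation_network(taxa, metab_matrix(v, "raw"), min_pairs = 10)
  expect_equal(res$taxon_id, "vary")
  un <- attr(res, "uncomputed")
  expect_identical(un$taxon_id, "flat")
  expect_match(un$reason, "constant")
})

test_that("planted monotone couplings are recovered and rho is rank-invariant", {
  ch <- small_cohort()
  abs_taxa <- estimate_absolute_abundance(ch$taxa)
  hits <- ch$truth$couplings$feature_id
  sub <- metab_matrix(ch$matrix$values[, hits, drop = FALSE], "raw")
  res <- correlation_network(abs_taxa, sub, min_pairs = 30)
  planted <- dplyr::inner_join(res, ch$truth$couplings,
                               by = c("taxon_id", "feature_id"))
  expect_true(all(planted$rho > 0.4))
  expect_true(all(planted$kept))

  # strictly monotone transform of the metabolite leaves rho unchanged
  cubed <- metab_matrix(sub$values^3, "raw")
  res2 <- correlation_network(abs_taxa, cubed, min_pairs = 30)
  expect_equal(res$rho, res2$rho, tolerance = 1e-12)
})

test_that("no imputation: complete-pair counts equal unmasked overlap exactly", {
  ch <- small_cohort()
  abs_taxa <- estimate_absolute_abundance(ch$taxa)
  res <- correlation_network(abs_taxa, ch$matrix, min_pairs = 20)
  shared <- intersect(rownames(abs_taxa), sample_ids(ch$matrix))
  obs <- colSums(!is.na(ch$matrix$values[shared, , drop = FALSE]))
  expect_equal(res$n_pairs, unname(obs[res$feature_id]))
})

test_that("Fisher r-to-z matches the closed form and is antisymmetric", {
  # rho_a = 0.5 (n=50) vs rho_b = 0 (n=50): z = atanh(0.5)/sqrt(2/47)
  z_expected <- atanh(0.5) / sqrt(1 / 47 + 1 / 47)
  expect_equal(z_expected, 2.66, tolerance = 1e-2)
  expect_equal(2 * pnorm(-abs(z_expected)), 0.0078, tolerance = 1e-2)

  withr::with_seed(14, {
    x <- c(rnorm(30), rnorm(30))
    y <- c(x[1:30] + rnorm(30), rnorm(30))
    g <- rep(c("A", "B"), each = 30)
    ab <- compare_correlation_subgroups(x, y, g)
    ba <- compare_correlation_subgroups(x, y, factor(g, levels = c("B", "A")))
    expect_equal(ab$z, -ba$z, tolerance = 1e-12)
    expect_equal(ab$p, ba$p, tolerance = 1e-12)
    # closed form recomputed independently from the reported rho/n
    z_oracle <- (atanh(ab$rho_a) - atanh(ab$rho_b)) /
      sqrt(1 / (ab$n_a - 3) + 1 / (ab$n_b - 3))
    expect_equal(ab$z, z_oracle, tolerance = 1e-12)
  })

  x <- 1:10
  y <- c(1:10, 10:1)
  g <- rep(c("A", "B"), each = 10)
  expect_error(compare_correlation_subgroups(c(x, x), y, g), "infinite")
})

test_that("equal subgroup correlations give z = 0, p = 1", {
  withr::with_seed(6, {
    x <- rnorm(40)
    y <- x + rnorm(40)
  })
  res <- compare_correlation_subgroups(c(x, x), c(y, y), rep(c("A", "B"), each = 40))
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
})

test_that("edge-strength contrast uses magnitudes and detects weak groups", {
  edges <- tibble::tibble(
    taxon_id = rep("t", 12),
    feature_id = rep(c("weak1", "weak2", "strong1", "strong2"), each = 3),
    rho = c(rep(c(0.1, -0.1, 0.12), 2), rep(c(0.6, -0.62, 0.58), 2))
  )
  res <- compare_edge_strength_groups(edges, c("weak1", "weak2"),
                                      c("strong1", "strong2"))
  expect_lt(res$p, 0.01)
  expect_lt(res$median_abs_rho_1, res$median_abs_rho_2)
  # sign flips leave the contrast unchanged
  res2 <- compare_edge_strength_groups(
    dplyr::mutate(edges, rho = -rho), c("weak1", "weak2"), c("strong1", "strong2")
  )
  expect_equal(res$p, res2$p)
  # identical magnitude multisets: U sits at its mean, p is large
  same <- compare_edge_strength_groups(edges, c("weak1", "strong1"),
                                       c("weak2", "strong2"))
  expect_gt(same$p, 0.8)
  expect_error(compare_edge_strength_groups(edges, "absent", "strong1"),
               "at least one")
})
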