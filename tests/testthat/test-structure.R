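canberra_oracle <- function(x, y) {
  d <- abs(x) + abs(y)
  sum(ifelse(d > 0, abs(x - y) / d, 0))
}

test_that("Canberra distance follows the |x|+|y| convention with 0/0 -> 0", {
  m <- rbind(a = c(1, 2, 0), b = c(3, 2, 0))
  D <- compute_distance(m, "canberra")
  expect_equal(D$D["a", "b"], 0.5) # |1-3|/(1+3), two zero terms
  expect_equal(D$D["a", "a"], 0)

  withr::with_seed(5, {
    X <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(letters[1:6], NULL))
    X[2, 3] <- 0
    X[5, 3] <- 0
    D <- compute_distance(X, "canberra")$D
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(D[i, j], canberra_oracle(X[i, ], X[j, ]))
    }
    expect_true(isSymmetric(D))
  })
})

test_that("Bray-Curtis: disjoint supports give distance 1, negatives error", {
  m <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(compute_distance(m, "bray_curtis")$D["a", "b"], 1)
  expect_error(compute_distance(rbind(a = c(-1, 2), b = c(1, 1)), "bray_curtis"),
               "non-negative")
})

all_orderings <- function(n) {
  do.call(rbind, combinat_permutations(n))
}

test_that("PERMANOVA exhaustive p equals the two-tight-pairs enumeration (1/3)", {
  X <- rbind(a = c(0, 0), b = c(0.01, 0), c = c(10, 10), d = c(10.01, 10))
  D <- compute_distance(X, "canberra")
  res <- permanova(D, c("g1", "g1", "g2", "g2"),
                   permutations = all_orderings(4))
  expect_equal(res$p, 1 / 3)
})

test_that("PERMANOVA pseudo-F matches vegan and sampled p tracks enumeration", {
  withr::with_seed(11, {
    X <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(letters[1:7], NULL))
    g <- c("a", "a", "a", "b", "b", "b", "b")
    D <- compute_distance(X, "canberra")
    res <- permanova(D, g, n_permutations = 2000, seed = 3)
    ref <- vegan::adonis2(stats::as.dist(D$D) ~ g,
                          data = data.frame(g = g), permutations = 99)
    expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
    exact <- permanova(D, g, permutations = all_orderings(7))
    expect_equal(res$p, exact$p, tolerance = 0.05)
    expect_gte(res$p, 1 / 2001) # +1 floor: never exactly zero
  })
})

test_that("PERMANOVA is invariant to joint sample/label reordering", {
  ch <- small_cohort()
  std <- preprocess_pipeline(ch$matrix)
  D <- compute_distance(std)
  g <- ch$metadata$outcome
  r1 <- permanova(D, g, n_permutations = 99, seed = 7)
  o <- rev(seq_along(g))
  r2 <- permanova(as_vm_dist(D$D[o, o]), g[o], n_permutations = 99, seed = 7)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-12)
})

test_that("PERMANOVA rejects degenerate groupings", {
  D <- compute_distance(matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL)))
  expect_error(permanova(D, rep("g", 4)), "two groups")
  expect_error(permanova(D, c("a", "b", "b", "b")), "two members")
})

test_that("Mantel: self-correlation is 1 and reordering leaves r unchanged", {
  ch <- small_cohort()
  std <- preprocess_pipeline(ch$matrix)
  D1 <- compute_distance(std)
  res <- mantel_test(D1, D1, n_permutations = 49, seed = 2)
  expect_equal(res$r, 1)
  expect_gte(res$p, 1 / 50)

  abs_taxa <- estimate_absolute_abundance(ch$taxa)
  shared <- intersect(sample_ids(std), rownames(abs_taxa))
  D1s <- as_vm_dist(D1$D[shared, shared])
  D2 <- compute_distance(abs_taxa[shared, ], "bray_curtis")
  r_ab <- mantel_test(D1s, D2, n_permutations = 9, seed = 1)$r
  o <- sample(seq_along(shared))
  r_perm <- mantel_test(as_vm_dist(D1s$D[o, o]), as_vm_dist(D2$D[o, o]),
                        n_permutations = 9, seed = 1)$r
  expect_equal(r_ab, r_perm, tolerance = 1e-12)
})

test_that("k-medoids: k=n degenerate case, planted blobs, determinism", {
  withr::with_seed(8, {
    blob1 <- matrix(rnorm(20, 2, 0.1), 10, 2)
    blob2 <- matrix(rnorm(20, 40, 0.5), 10, 2)
    X <- rbind(blob1, blob2)
    rownames(X) <- sprintf("s%02d", 1:20)
    D <- compute_distance(X, "canberra")
    fit <- kmedoids_fit(D, 2)
    truth <- rep(1:2, each = 10)
    expect_equal(match_clusters(setNames(truth, rownames(X)), fit$assignment)$matched_fraction, 1)
    fit2 <- kmedoids_fit(D, 2)
    expect_identical(fit$assignment, fit2$assignment)

    all_own <- kmedoids_fit(D, 20)
    expect_equal(all_own$W, 0)
    expect_equal(length(unique(all_own$assignment)), 20L)
    expect_error(kmedoids_fit(D, 21), "k must lie")
  })
})

test_that("gap curve covers the k range and W is non-increasing in k", {
  ch <- small_cohort()
  std <- preprocess_pipeline(ch$matrix)
  gap <- select_k_gap(std, k_range = 1:6, B = 10, seed = 2)
  expect_equal(nrow(gap$curve), 6L)
  expect_true(all(diff(gap$curve$W) <= 1e-8))
  expect_true(gap$chosen_k %in% 1:6)
  expect_identical(tidy(gap), gap$curve)
  expect_error(
    select_k_gap(matrix(1, 5, 3, dimnames = list(letters[1:5], NULL)), B = 10),
    "degenerate"
  )
})

test_that("cluster matching: label permutation, one moved sample, surplus labels", {
  ref <- setNames(rep(1:3, each = 4), sprintf("s%02d", 1:12))
  renamed <- setNames(c(7, 9, 5)[ref], names(ref))
  expect_equal(match_clusters(ref, renamed)$matched_fraction, 1)

  moved <- renamed
  moved[1] <- 9
  expect_equal(match_clusters(ref, moved)$matched_fraction, 11 / 12)

  # 3 new labels vs 2 reference labels: brute-force oracle over injections
  withr::with_seed(3, {
    ref2 <- setNames(sample(1:2, 15, replace = TRUE), sprintf("t%02d", 1:15))
    new2 <- setNames(sample(1:3, 15, replace = TRUE), names(ref2))
    got <- match_clusters(ref2, new2)
    counts <- table(new2, ref2)
    expect_equal(got$matched_fraction, brute_force_best_overlap(counts) / 15)
  })
})

test_that("robustness: fraction 1 is exact, score is relabeling-invariant", {
  ch <- small_cohort()
  std <- preprocess_pipeline(ch$matrix)
  D <- compute_distance(std)
  fit <- kmedoids_fit(D, 3)
  rob <- cluster_robustness(D, fit, n_subsamples = 5, fraction = 1, seed = 9)
  expect_equal(rob$accuracies, rep(1, 5))
  expect_equal(rob$mean_accuracy, 1)
  expect_equal(rob$n_above_95, 5L)

  relab <- fit
  relab$assignment <- setNames(c(30, 10, 20)[fit$assignment], names(fit$assignment))
  rob2 <- cluster_robustness(D, relab, n_subsamples = 5, fraction = 0.8, seed = 9)
  rob3 <- cluster_robustness(D, fit, n_subsamples = 5, fraction = 0.8, seed = 9)
  expect_equal(rob2$accuracies, rob3$accuracies)
  expect_error(cluster_robustness(D, fit, fraction = 1.2), "fraction")
})

test_that("Fisher contingency: [[2,0],[0,2]] gives p = 1/3 and is symmetric", {
  a <- c("x", "x", "y", "y")
  b <- c("u", "u", "v", "v")
  res <- contingency_association(a, b)
  row <- res[res$level_a == "x" & res$level_b == "u", ]
  expect_equal(row$p, 1 / 3, tolerance = 1e-12)
  swapped <- contingency_association(b, a)
  expect_equal(sort(res$p), sort(swapped$p), tolerance = 1e-12)
})

test_that("contingency scan respects a scope filter and reports q-values", {
  ch <- small_cohort()
  res <- contingency_association(ch$truth$cst, ch$metadata$outcome,
                                 scope = ch$metadata$race == "Black")
  expect_true(all(res$q >= res$p - 1e-12 | res$q <= 1))
  expect_true(all(res$n11 + res$n10 + res$n01 + res$n00 ==
                    sum(ch$metadata$race == "Black")))
})
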