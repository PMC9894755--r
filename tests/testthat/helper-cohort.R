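# Shared fixtures, generated in code and memoized per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# A small cohort with planted effects and couplings, reused across files.
small_cohort <- function() {
  fixture("small_cohort", {
    cfg <- sim_config(
      n_samples = 90L, n_cases = 30L, n_taxa = 20L,
      n_named = 50L, n_unnamed = 10L, n_clusters = 3L,
      effects = sim_effects(4, shift = 1.2),
      couplings = sim_couplings(3, strength = 0.7, taxon_idx = c(1L, 3L, 5L),
                                feature_from = 41L),
      seed = 42L
    )
    generate_cohort(cfg)
  })
}

# A tiny hand-made metabolite matrix with one masked cell.
toy_matrix <- function() {
  v <- matrix(c(1, 10, 100, 2, NA, 200), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("fa", "fb")))
  metab_matrix(v, scale_tag = "raw")
}

# Minimal consistent metadata for n samples.
toy_metadata <- function(n, n_case = floor(n / 3), seed = 1) {
  withr::with_seed(seed, {
    outcome <- rep("TB", n)
    outcome[seq_len(n_case)] <- "sPTB"
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      outcome = outcome,
      gab_weeks = ifelse(outcome == "sPTB", runif(n, 25, 36.5), runif(n, 38, 41)),
      race = sample(c("Black", "White"), n, replace = TRUE, prob = c(0.7, 0.3)),
      age_years = round(runif(n, 20, 40)),
      bmi = round(runif(n, 20, 40), 1),
      nulliparous = runif(n) < 0.4,
      ptb_history = runif(n) < 0.25,
      progesterone = runif(n) < 0.15,
      batch = "B1"
    )
  })
}

# Brute-force assignment oracle: best total overlap over all injections of
# row labels into column labels (small tables only).
brute_force_best_overlap <- function(counts) {
  nr <- nrow(counts)
  nc <- ncol(counts)
  if (nr <= nc) {
    perms <- combinat_permutations(nc)
    best <- 0
    for (p in perms) {
      s <- sum(counts[cbind(seq_len(nr), p[seq_len(nr)])])
      best <- max(best, s)
    }
  } else {
    perms <- combinat_permutations(nr)
    best <- 0
    for (p in perms) {
      idx <- cbind(p[seq_len(nc)], seq_len(nc))
      best <- max(best, sum(counts[idx]))
    }
  }
  best
}

combinat_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_permutations(n - 1)) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}
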