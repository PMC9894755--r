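#' Simulation configuration for a synthetic pregnancy cohort
#'
#' Encodes the generative model the analyses assume: a two-group outcome
#' (sPTB versus term) with a majority-Black race mix, community-state-type
#' (CST) structured, strongly skewed taxa compositions with log-normal 16S
#' total loads, a metabolome with planted sample-cluster block structure on
#' the log scale, left-censored (detection-limit) missingness, and optional
#' planted outcome effects, microbe-metabolite couplings, and enriched
#' annotation sets, all recorded in a ground-truth object.
#'
#' @param n_samples,n_cases cohort size and number of sPTB cases.
#' @param p_black,p_white race mix (the remainder is "Other").
#' @param n_taxa number of taxa.
#' @param n_named,n_unnamed named metabolites and unnamed spectral features.
#' @param n_clusters number of planted metabolome sample clusters.
#' @param cluster_separation block offset in units of the feature SD.
#' @param cluster_feature_frac fraction of features carrying each cluster's
#'   block offset.
#' @param cst_probs named CST mixing probabilities.
#' @param load_meanlog,load_sdlog log-normal parameters of the total 16S
#'   copy number.
#' @param load_missing_frac fraction of samples lacking a qPCR load value.
#' @param censor_frac fraction of features subject to left-censoring.
#' @param censor_max maximal per-feature censoring quantile (each censored
#'   feature draws its detection threshold at a uniform quantile below
#'   this).
#' @param ptb_history_or odds ratio tilting case sampling toward women with
#'   a PTB history (the planted weak clinical signal).
#' @param effects tibble (`feature_id`, `stratum`, `shift`, `xenobiotic`)
#'   of planted case shifts in SD units; see [sim_effects()].
#' @param couplings tibble (`taxon_id`, `feature_id`, `strength`) of
#'   planted monotone microbe-metabolite couplings; see [sim_couplings()].
#' @param enriched_sets tibble (`set_id`, `n_members`, `shift`) of planted
#'   enriched sub-pathway sets.
#' @param n_batches,batch_offsets processing batches and their additive
#'   log-scale offsets.
#' @param seed master seed; every draw flows from named substreams of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 232L, n_cases = 80L,
                       p_black = 0.71, p_white = 0.24,
                       n_taxa = 40L, n_named = 150L, n_unnamed = 30L,
                       n_clusters = 6L, cluster_separation = 3,
                       cluster_feature_frac = 0.4,
                       cst_probs = c(I = 0.35, II = 0.07, III = 0.28, IV = 0.25, V = 0.05),
                       load_meanlog = log(1e7), load_sdlog = 1,
                       load_missing_frac = 0.06,
                       censor_frac = 0.6, censor_max = 0.45,
                       ptb_history_or = 3,
                       effects = NULL, couplings = NULL, enriched_sets = NULL,
                       n_batches = 2L, batch_offsets = c(0, 0),
                       seed = 1L) {
  if (n_cases >= n_samples) abort_vagmet("n_cases must be smaller than n_samples")
  cfg <- list(
    n_samples = as.integer(n_samples), n_cases = as.integer(n_cases),
    p_black = p_black, p_white = p_white,
    n_taxa = as.integer(n_taxa), n_named = as.integer(n_named),
    n_unnamed = as.integer(n_unnamed),
    n_clusters = as.integer(n_clusters),
    cluster_separation = cluster_separation,
    cluster_feature_frac = cluster_feature_frac,
    cst_probs = cst_probs,
    load_meanlog = load_meanlog, load_sdlog = load_sdlog,
    load_missing_frac = load_missing_frac,
    censor_frac = censor_frac, censor_max = censor_max,
    ptb_history_or = ptb_history_or,
    effects = effects %||% tibble(feature_id = character(), stratum = character(),
                                  shift = numeric(), xenobiotic = logical()),
    couplings = couplings %||% tibble(taxon_id = character(), feature_id = character(),
                                      strength = numeric()),
    enriched_sets = enriched_sets %||% tibble(set_id = character(),
                                              n_members = integer(), shift = numeric()),
    n_batches = as.integer(n_batches), batch_offsets = batch_offsets,
    seed = as.integer(seed)
  )
  bad <- setdiff(cfg$effects$feature_id, sim_feature_ids(cfg))
  if (length(bad) > 0L) {
    abort_vagmet(sprintf("planted effect on unknown feature(s): %s",
                         paste(head(bad, 5L), collapse = ", ")))
  }
  if (nrow(cfg$effects) > cfg$n_named + cfg$n_unnamed) {
    abort_vagmet("more planted effects than features")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Deterministic feature and taxon identifiers of a simulated cohort
#'
#' @param config a [sim_config()].
#' @return Character vector of feature ids (named metabolites `met_XXXX`
#'   followed by unnamed spectral features `unk_XXXX`).
#' @export
sim_feature_ids <- function(config) {
  c(sprintf("met_%04d", seq_len(config$n_named)),
    sprintf("unk_%04d", seq_len(config$n_unnamed)))
}

#' @rdname sim_feature_ids
#' @export
sim_taxon_ids <- function(config) {
  base <- c("Lactobacillus_crispatus", "Lactobacillus_gasseri",
            "Lactobacillus_iners", "Lactobacillus_jensenii",
            "Gardnerella_vaginalis", "Atopobium_vaginae",
            "Prevotella_bivia", "Sneathia_amnii", "Megasphaera_sp",
            "Mobiluncus_curtisii")
  n <- config$n_taxa
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("taxon_%03d", seq_len(n - length(base))))
}

#' Convenience constructors for planted truth
#'
#' `sim_effects()` places `n` case shifts of `shift` SD units on consecutive
#' named features starting at `from`; `sim_couplings()` couples features to
#' taxa with the given monotone strength (the latent correlation of the
#' feature's log level with the taxon's log absolute abundance).
#'
#' @param n number of planted features.
#' @param shift case shift in feature-SD units.
#' @param stratum `"all"`, `"Black"` or `"White"`.
#' @param xenobiotic flag features as taxa-independent xenobiotic-like.
#' @param from index of the first named feature used.
#' @return A tibble suitable for [sim_config()].
#' @export
sim_effects <- function(n, shift = 0.8, stratum = "all", xenobiotic = FALSE,
                        from = 1L) {
  tibble(
    feature_id = sprintf("met_%04d", seq.int(from, from + n - 1L)),
    stratum = stratum, shift = shift, xenobiotic = xenobiotic
  )
}

#' @rdname sim_effects
#' @param taxon_idx,feature_from taxon indices and first feature index used.
#' @param strength latent monotone coupling strength in `[0, 1)`.
#' @export
sim_couplings <- function(n, strength = 0.6, taxon_idx = NULL, feature_from = 51L) {
  taxon_idx <- taxon_idx %||% (seq_len(n) %% 10L + 1L)
  base <- c("Lactobacillus_crispatus", "Lactobacillus_gasseri",
            "Lactobacillus_iners", "Lactobacillus_jensenii",
            "Gardnerella_vaginalis", "Atopobium_vaginae",
            "Prevotella_bivia", "Sneathia_amnii", "Megasphaera_sp",
            "Mobiluncus_curtisii")
  tibble(
    taxon_id = base[taxon_idx],
    feature_id = sprintf("met_%04d", seq.int(feature_from, feature_from + n - 1L)),
    strength = strength
  )
}

# Triangular(lo, hi, mode) sampler via inverse CDF.
rtriangular <- function(n, lo, hi, mode) {
  u <- runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' Draws a full paired cohort from the generative model described in
#' [sim_config()]: metadata (outcome, gestational age at birth, race,
#' clinical covariates, batch, CST), CST-structured taxa compositions with
#' log-normal total loads, and a raw metabolite matrix with planted cluster
#' structure, case shifts, taxon couplings and left-censored missingness.
#' Identical seeds give byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @return A list: `matrix` (raw [metab_matrix()]), `taxa`
#'   ([taxa_table()]), `metadata` (tibble), `annotations` (tibble), and
#'   `truth` (every planted effect, coupling, set, and the sample-cluster
#'   assignment).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  feat_ids <- sim_feature_ids(config)
  n_feat <- length(feat_ids)
  taxon_ids <- sim_taxon_ids(config)
  sample_id <- sprintf("S%04d", seq_len(n))

  with_seed(substream_seed(config$seed, "cohort"), {
    ## --- metadata ---------------------------------------------------------
    race <- sample(c("Black", "White", "Other"), n, replace = TRUE,
                   prob = c(config$p_black, config$p_white,
                            max(0, 1 - config$p_black - config$p_white)))
    ptb_history <- runif(n) < 0.22
    progesterone <- runif(n) < 0.15
    nulliparous <- runif(n) < 0.36
    age_years <- round(pmax(18, rnorm(n, 29, 6)))
    bmi <- round(pmax(16, rnorm(n, 30, 7)), 1)
    batch <- sample(sprintf("B%d", seq_len(config$n_batches)), n, replace = TRUE)
    w <- exp(log(config$ptb_history_or) * ptb_history)
    case_idx <- sample.int(n, config$n_cases, prob = w)
    outcome <- rep("TB", n)
    outcome[case_idx] <- "sPTB"
    gab_weeks <- numeric(n)
    gab_weeks[outcome == "TB"] <- runif(sum(outcome == "TB"), 38, 41)
    gab_weeks[outcome == "sPTB"] <- rtriangular(sum(outcome == "sPTB"), 21, 36.9, 35)

    ## --- microbiome -------------------------------------------------------
    cst <- sample(names(config$cst_probs), n, replace = TRUE, prob = config$cst_probs)
    dominant <- c(I = 1L, II = 2L, III = 3L, V = 4L)
    rel <- matrix(0, n, config$n_taxa, dimnames = list(sample_id, taxon_ids))
    for (i in seq_len(n)) {
      alpha <- rep(0.05, config$n_taxa)
      if (cst[i] %in% names(dominant)) {
        alpha[dominant[[cst[i]]]] <- 25
      } else { # diverse, anaerobe-rich community
        alpha[5:config$n_taxa] <- 0.6
      }
      rel[i, ] <- rdirichlet1(alpha)
    }
    total_load <- rlnorm(n, config$load_meanlog, config$load_sdlog)
    names(total_load) <- sample_id
    load_na <- sample.int(n, round(config$load_missing_frac * n))
    total_load[load_na] <- NA_real_
    abs_full <- sweep(rel, 1L, ifelse(is.na(total_load),
                                      exp(config$load_meanlog), total_load), "*")

    ## --- metabolome -------------------------------------------------------
    cluster <- sample.int(config$n_clusters, n, replace = TRUE)
    mu_f <- rnorm(n_feat, 5, 1)
    sigma_f <- runif(n_feat, 0.3, 0.8)

    ## planted enriched sets become extra case-shifted features; membership
    ## is fixed here so planted features can be kept out of the cluster
    ## blocks below (planted shifts and couplings are expressed on the
    ## realized per-feature SD scale, not diluted by block variance)
    effects <- config$effects
    set_truth <- list()
    used <- unique(effects$feature_id)
    pool <- setdiff(feat_ids[seq_len(config$n_named)], used)
    for (si in seq_len(nrow(config$enriched_sets))) {
      es <- config$enriched_sets[si, ]
      members <- pool[seq_len(es$n_members)]
      pool <- setdiff(pool, members)
      effects <- bind_rows(effects, tibble(
        feature_id = members, stratum = "all", shift = es$shift, xenobiotic = FALSE
      ))
      set_truth[[length(set_truth) + 1L]] <- tibble(
        set_id = es$set_id, feature_id = members, shift = es$shift
      )
    }
    set_truth <- bind_rows(set_truth)
    planted_idx <- match(unique(c(effects$feature_id, config$couplings$feature_id)),
                         feat_ids)

    block <- matrix(0, config$n_clusters, n_feat)
    for (c_i in seq_len(config$n_clusters)) {
      hit <- sample.int(n_feat, round(config$cluster_feature_frac * n_feat))
      block[c_i, hit] <- sample(c(-1, 1), length(hit), replace = TRUE) *
        config$cluster_separation
    }
    if (length(planted_idx) > 0L) block[, planted_idx] <- 0
    eps <- matrix(rnorm(n * n_feat), n, n_feat)
    for (ci in seq_len(nrow(config$couplings))) {
      cp <- config$couplings[ci, ]
      f <- match(cp$feature_id, feat_ids)
      t <- match(cp$taxon_id, taxon_ids)
      if (is.na(f) || is.na(t)) abort_vagmet("coupling references unknown feature/taxon")
      zt <- as.numeric(scale(log10(abs_full[, t] + 1)))
      s <- cp$strength
      eps[, f] <- sqrt(1 - s^2) * eps[, f] + s * zt
    }
    logv <- matrix(mu_f, n, n_feat, byrow = TRUE) +
      (block[cluster, , drop = FALSE] + eps) *
      matrix(sigma_f, n, n_feat, byrow = TRUE)

    for (ei in seq_len(nrow(effects))) {
      ef <- effects[ei, ]
      f <- match(ef$feature_id, feat_ids)
      in_stratum <- switch(ef$stratum,
        all = rep(TRUE, n),
        Black = race == "Black",
        White = race == "White",
        abort_vagmet(sprintf("unknown effect stratum: %s", ef$stratum))
      )
      hit <- in_stratum & outcome == "sPTB"
      logv[hit, f] <- logv[hit, f] + ef$shift * sigma_f[f]
    }

    batch_off <- setNames(rep_len(config$batch_offsets, config$n_batches),
                          sprintf("B%d", seq_len(config$n_batches)))
    logv <- logv + batch_off[batch]
    raw <- 10^logv
    dimnames(raw) <- list(sample_id, feat_ids)

    ## left-censoring: value below the feature's detection threshold => missing
    censor_q <- rep(0, n_feat)
    cens <- runif(n_feat) < config$censor_frac
    censor_q[cens] <- runif(sum(cens), 0, config$censor_max)
    for (f in which(censor_q > 0)) {
      thr <- quantile(raw[, f], censor_q[f], names = FALSE)
      raw[raw[, f] < thr, f] <- NA_real_
    }

    ## --- annotations ------------------------------------------------------
    supers <- c("Amino Acid", "Lipid", "Nucleotide", "Carbohydrate",
                "Xenobiotics", "Cofactors and Vitamins", "Peptide", "Energy")
    subs_per_super <- 3L
    named <- c(rep(TRUE, config$n_named), rep(FALSE, config$n_unnamed))
    super_pathway <- sample(supers, n_feat, replace = TRUE)
    xeno_ids <- effects$feature_id[effects$xenobiotic]
    super_pathway[feat_ids %in% xeno_ids] <- "Xenobiotics"
    sub_pathway <- paste0(super_pathway, " sub",
                          sample.int(subs_per_super, n_feat, replace = TRUE))
    if (nrow(set_truth) > 0L) {
      for (sid in unique(set_truth$set_id)) {
        members <- set_truth$feature_id[set_truth$set_id == sid]
        sub_pathway[feat_ids %in% members] <- sid
      }
    }
    sub_pathway[!named] <- NA_character_
    super_pathway[!named] <- NA_character_
    kegg_pool <- sprintf("map%05d", sample.int(99999, 30))
    kegg_ids <- vapply(seq_len(n_feat), function(f) {
      if (named[f] && runif(1) < 0.6) {
        paste(sample(kegg_pool, sample.int(2L, 1L)), collapse = ";")
      } else ""
    }, character(1L))
    annotations <- tibble(
      feature_id = feat_ids,
      display_name = ifelse(named, gsub("met_", "metabolite ", feat_ids),
                            gsub("unk_", "X - ", feat_ids)),
      named_flag = named,
      super_pathway = super_pathway,
      sub_pathway = sub_pathway,
      kegg_ids = kegg_ids,
      platform_tag = "LC-MS/MS"
    )

    metadata <- cohort_metadata(tibble(
      sample_id = sample_id, outcome = outcome, gab_weeks = gab_weeks,
      race = race, age_years = age_years, bmi = bmi,
      nulliparous = nulliparous, ptb_history = ptb_history,
      progesterone = progesterone, batch = batch, cst = cst
    ))

    list(
      matrix = metab_matrix(raw, scale_tag = "raw"),
      taxa = taxa_table(rel, total_load = total_load[!is.na(total_load)]),
      metadata = metadata,
      annotations = annotations,
      truth = list(
        effects = effects,
        couplings = config$couplings,
        enriched_sets = set_truth,
        clusters = setNames(cluster, sample_id),
        cst = setNames(cst, sample_id),
        censor_quantiles = setNames(censor_q, feat_ids),
        feature_sigma = setNames(sigma_f, feat_ids)
      )
    )
  })
}

#' Generate an external validation cohort with partial feature overlap
#'
#' Draws a cohort from the same generative family under its own seed, keeps
#' a random subset of the reference feature universe of the requested
#' overlap, and applies a global location/scale batch shift on the log
#' scale, emulating an independently processed external metabolome dataset.
#'
#' @param config a [sim_config()] (the external cohort's own sizes apply).
#' @param reference_features feature ids of the reference (training)
#'   universe.
#' @param overlap_fraction fraction of reference features measured
#'   externally, in `(0, 1]`.
#' @param location,scale global log10-scale batch shift.
#' @param seed seed for the external draw.
#' @return A list: `matrix` (raw [metab_matrix()] on the overlapping
#'   features), `metadata`, and `overlap` (the realized fraction).
#' @export
generate_external_cohort <- function(config, reference_features,
                                     overlap_fraction, location = 0.3,
                                     scale = 1.1, seed = 99L) {
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    abort_vagmet("overlap_fraction must lie in (0, 1]")
  }
  cfg <- config
  cfg$seed <- as.integer(seed)
  cohort <- generate_cohort(cfg)
  keep <- with_seed(substream_seed(seed, "external_overlap"), {
    sample(reference_features, round(overlap_fraction * length(reference_features)))
  })
  keep <- intersect(feature_ids(cohort$matrix), keep)
  v <- cohort$matrix$values[, keep, drop = FALSE]
  v <- 10^(location + scale * log10(v))
  list(
    matrix = metab_matrix(v, scale_tag = "raw"),
    metadata = cohort$metadata,
    overlap = length(keep) / length(reference_features)
  )
}
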