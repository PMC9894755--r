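# FNV-1a hash of a JSON-serialized object, for cheap config fingerprints.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the configuration-driven analysis pipeline
#'
#' Executes the requested stages in dependency order — `simulate` (or
#' reading the provided input tables), `preprocess`, `cluster`,
#' `associate`, `enrich`, `network` — writing each stage's artifacts under
#' the output directory and a manifest recording the config hash, seed,
#' package version and per-stage status. A rerun with an unchanged config
#' skips stages whose outputs already exist (recorded as cache hits);
#' per-stage seeds derive from the master seed by stage name, so adding a
#' stage never perturbs another stage's randomness.
#'
#' @param config a list: `outdir`, `seed`, `stages` (subset of the above,
#'   in any order), optional `sim` ([sim_config()] arguments), and
#'   per-stage parameter lists (`cluster`, `associate`, `enrich`,
#'   `network`).
#' @return The manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stages_all <- c("simulate", "preprocess", "cluster", "associate", "enrich", "network")
  stages <- intersect(stages_all, config$stages %||% stages_all)
  outdir <- config$outdir %||% abort_vagmet("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  hash <- config_hash(config[setdiff(names(config), "outdir")])
  manifest_path <- file.path(outdir, "manifest.json")
  old_hash <- NULL
  if (file.exists(manifest_path)) {
    old_hash <- tryCatch(jsonlite::read_json(manifest_path)$config_hash,
                         error = function(e) NULL)
  }
  cache_ok <- identical(old_hash, hash)
  manifest <- list(
    config_hash = hash, seed = seed,
    version = as.character(utils::packageVersion("vagmet")),
    stages = list()
  )
  art <- function(...) file.path(outdir, ...)
  note <- function(stage, status, outputs) {
    manifest$stages[[stage]] <<- list(status = status, outputs = outputs)
  }

  state <- new.env(parent = emptyenv())
  load_cohort <- function() {
    if (is.null(state$cohort)) {
      parsed <- read_metabolite_matrix(art("raw_metabolites.tsv"))
      state$cohort <- list(
        matrix = parsed$matrix,
        taxa = read_taxa_table(art("taxa.tsv"), art("loads.tsv")),
        metadata = cohort_metadata(read_report(art("metadata.tsv"))),
        annotations = as_tibble(read.delim(art("annotations.tsv")))
      )
    }
    state$cohort
  }

  for (stage in stages) {
    stage_seed <- substream_seed(seed, paste0("stage_", stage))
    outputs <- switch(stage,
      simulate = c("raw_metabolites.tsv", "taxa.tsv", "loads.tsv",
                   "metadata.tsv", "annotations.tsv"),
      preprocess = c("standardized.tsv", "detection_summary.json"),
      cluster = "clusters.json",
      associate = "associations.tsv",
      enrich = "enrichment.tsv",
      network = "network_edges.tsv"
    )
    if (cache_ok && all(file.exists(art(outputs)))) {
      note(stage, "cached", outputs)
      next
    }
    upstream_needed <- stage != "simulate"
    if (upstream_needed && !file.exists(art("raw_metabolites.tsv"))) {
      abort_vagmet(sprintf("stage '%s' needs upstream outputs; run 'simulate' first", stage))
    }
    switch(stage,
      simulate = {
        cfg <- do.call(sim_config, modifyList(config$sim %||% list(),
                                              list(seed = stage_seed)))
        cohort <- generate_cohort(cfg)
        state$cohort <- cohort
        write_metabolite_matrix(cohort$matrix, art("raw_metabolites.tsv"))
        write_taxa_table(cohort$taxa, art("taxa.tsv"), art("loads.tsv"))
        write_report(cohort$metadata, art("metadata.tsv"), "tsv")
        write_report(cohort$annotations, art("annotations.tsv"), "tsv")
      },
      preprocess = {
        ch <- load_cohort()
        std <- robust_standardize(log10_transform(ch$matrix))
        state$std <- std
        write_metabolite_matrix(std, art("standardized.tsv"))
        ds <- detection_summary(ch$matrix, ch$annotations)
        write_report(ds[c("n_features_total", "n_named", "n_unnamed",
                          "n_detected_over_half", "n_detected_in_all")],
                     art("detection_summary.json"), "json")
      },
      cluster = {
        ch <- load_cohort()
        std <- state$std %||% robust_standardize(log10_transform(ch$matrix))
        complete <- min_impute(std)
        pc <- config$cluster %||% list()
        gap <- select_k_gap(complete, k_range = seq_len(pc$kmax %||% 15L),
                            B = pc$B %||% 50L, seed = stage_seed)
        rob <- cluster_robustness(compute_distance(complete), gap$fit,
                                  n_subsamples = pc$n_subsamples %||% 100L,
                                  fraction = pc$fraction %||% 0.9,
                                  seed = stage_seed)
        write_report(list(
          chosen_k = gap$chosen_k, argmax_k = gap$argmax_k,
          curve = gap$curve,
          assignment = as.list(gap$fit$assignment),
          robustness = list(mean_accuracy = rob$mean_accuracy,
                            n_above_95 = rob$n_above_95,
                            accuracies = rob$accuracies)
        ), art("clusters.json"), "json")
      },
      associate = {
        ch <- load_cohort()
        pc <- config$associate %||% list()
        res <- association_scan(ch$matrix, ch$metadata,
                                strata = pc$strata %||% c("all", "Black", "White"))
        write_report(res, art("associations.tsv"), "tsv")
      },
      enrich = {
        ch <- load_cohort()
        pc <- config$enrich %||% list()
        sets <- build_metabolite_sets(ch$annotations)
        res <- set_enrichment_scan(ch$matrix, ch$metadata, sets,
                                   n_permutations = pc$n_permutations %||% 1000L,
                                   seed = stage_seed)
        write_report(res, art("enrichment.tsv"), "tsv")
      },
      network = {
        ch <- load_cohort()
        pc <- config$network %||% list()
        abs_taxa <- estimate_absolute_abundance(ch$taxa)
        feats <- pc$features %||% feature_ids(ch$matrix)
        sub <- metab_matrix(ch$matrix$values[, feats, drop = FALSE], "raw")
        edges <- correlation_network(abs_taxa, sub,
                                     min_pairs = pc$min_pairs,
                                     min_pair_fraction = pc$min_pair_fraction %||% 0.22)
        write_report(edges, art("network_edges.tsv"), "tsv")
      }
    )
    note(stage, "computed", outputs)
  }
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
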