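# End-to-end pipeline: simulate -> process -> fitness -> network -> cluster,
# driven by a single validated configuration and a single seed.

.config_defaults <- function() {
  list(
    seed = 1L,
    # simulation
    depth = 1e6, alpha = 1, error_rate = 0.001, abundance_sigma = 0.5,
    offsets = 0:4, replicates = 3L, qual_high = 38L, qual_low = 20L,
    low_qual_frac = 0.05, read_length = 150L, noise_scale = 0.05,
    gate_floor = 0.4, simulate_reads = FALSE, landscape_subset = 0L,
    # read processing
    trim_first = 20L, trim_last = 114L, min_qual = 28L,
    qual_mode = "all_bases", min_count = 10L, min_reads_corr = 4L,
    # fitness / classes
    strong = 0.6, weak = 0.2, wt_parS = WT_PARS, wt_NBS = WT_NBS,
    # network
    mode = "aa", codon_model = "NNS", target = WT_NBS, shuffles = 1000L,
    max_steps = 8L,
    # clustering
    kd_cap = 10000
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults (trim window 20-114, minimum Phred 28, pooled minimum
#' count 10, class thresholds 0.6/0.2, 1000 edge shuffles, ...), rejects
#' unknown keys and checks types and ranges before any stage runs.
#'
#' @param config named list of overrides (possibly empty); or a path to a
#'   JSON or YAML file containing one.
#' @return A validated `b1h_config` list.
#' @export
#' @examples
#' validate_config(list(depth = 1e4, shuffles = 50))$min_count
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  num_pos <- c(depth = cfg$depth, replicates = cfg$replicates,
               shuffles = cfg$shuffles)
  for (k in names(num_pos)) {
    if (!is.numeric(num_pos[[k]]) || num_pos[[k]] < 1) {
      stop(sprintf("config error: '%s' must be a positive number", k))
    }
  }
  for (k in c("strong", "weak", "low_qual_frac", "gate_floor")) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1) {
      stop(sprintf("config error: '%s' must lie in [0, 1]", k))
    }
  }
  if (cfg$weak > cfg$strong) stop("config error: weak threshold > strong")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    stop("config error: 'error_rate' must lie in [0, 1)")
  }
  if (cfg$trim_first < 1 || cfg$trim_first > cfg$trim_last) {
    stop("config error: trim window must satisfy 1 <= first <= last")
  }
  if (cfg$min_qual < 0) stop("config error: 'min_qual' must be >= 0")
  if (cfg$landscape_subset < 0) {
    stop("config error: 'landscape_subset' must be >= 0")
  }
  if (!cfg$qual_mode %in% c("all_bases", "mean")) {
    stop("config error: 'qual_mode' must be 'all_bases' or 'mean'")
  }
  if (!cfg$mode %in% c("aa", "nt")) {
    stop("config error: 'mode' must be 'aa' or 'nt'")
  }
  if (!cfg$codon_model %in% c("NNS", "full_standard")) {
    stop("config error: 'codon_model' must be 'NNS' or 'full_standard'")
  }
  .validate_variants(c(cfg$wt_parS, cfg$wt_NBS, cfg$target))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "b1h_config")
}

.run_stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "] running")
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate, (optionally) read emission + processing, fitness
#' scoring and classification, sequence-space network and shortest-path
#' analysis with its shuffle null, and K_D clustering, writing per-stage
#' outputs and a machine-readable summary to `outdir`. Deterministic given
#' the configured seed; every output is listed in a manifest that carries
#' the configuration hash.
#'
#' With `simulate_reads = TRUE` the simulated counts are written out as
#' FASTQ reads and re-decoded by the read processor (the full path; use a
#' modest `depth`); otherwise the simulated counts feed the fitness stage
#' directly.
#'
#' @param config configuration overrides (list or file path); see
#'   [validate_config()].
#' @param outdir output directory.
#' @param quiet suppress stage messages.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("b1h_run_"),
                         quiet = FALSE) {
  cfg <- if (inherits(config, "b1h_config")) config else validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(cfg))
  summary <- list(config_hash = cfg_hash, seed = cfg$seed)

  truth <- .run_stage("simulate", quiet, {
    tl <- build_truth_landscape(default_truth_rules(gate_floor = cfg$gate_floor),
                                noise_scale = cfg$noise_scale,
                                seed = .stage_seed(cfg$seed, 11L))
    if (cfg$landscape_subset > 0) {
      # desk-scale runs: restrict to a random variant subset (anchors and
      # target always kept) so per-variant depth stays realistic
      set.seed(.stage_seed(cfg$seed, 13L))
      keep <- union(c(cfg$wt_parS, cfg$wt_NBS, cfg$target),
                    sample(tl$variant, min(cfg$landscape_subset, nrow(tl))))
      sub <- tl[match(keep, tl$variant), ]
      rownames(sub) <- NULL
      tl <- structure(sub, rules = attr(tl, "rules"),
                      noise_scale = attr(tl, "noise_scale"),
                      seed = attr(tl, "seed"),
                      class = c("truth_landscape", "data.frame"))
    }
    tl
  })
  sim_cfg <- sim_config(depth = cfg$depth, alpha = cfg$alpha,
                        error_rate = cfg$error_rate, offsets = cfg$offsets,
                        replicates = cfg$replicates,
                        abundance_sigma = cfg$abundance_sigma,
                        qual_high = cfg$qual_high, qual_low = cfg$qual_low,
                        low_qual_frac = cfg$low_qual_frac,
                        read_length = cfg$read_length,
                        seed = .stage_seed(cfg$seed, 12L))
  counts <- .run_stage("simulate", quiet, {
    simulate_selection_counts(truth, sim_cfg)
  })
  utils::write.table(truth, file.path(outdir, "truth_landscape.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  diagnostics <- NULL
  if (isTRUE(cfg$simulate_reads)) {
    proc <- .run_stage("process", quiet, {
      manifest <- emit_reads(counts, sim_cfg, file.path(outdir, "reads"))
      process_reads(manifest, min_count = cfg$min_count,
                    trim_first = cfg$trim_first, trim_last = cfg$trim_last,
                    min_qual = cfg$min_qual, qual_mode = cfg$qual_mode)
    })
    counts <- proc$counts
    diagnostics <- proc$diagnostics
    summary$read_tallies <- proc$diagnostics
  }
  write_count_table(counts, file.path(outdir, "counts.tsv"))

  fit <- .run_stage("fitness", quiet, {
    fitness_scores(counts, min_count = cfg$min_count, wt_parS = cfg$wt_parS,
                   wt_NBS = cfg$wt_NBS, strong = cfg$strong, weak = cfg$weak)
  })
  utils::write.table(fit, file.path(outdir, "fitness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cp <- count_and_pool(counts, min_count = cfg$min_count)
  summary$n_variants_observed <- nrow(counts)
  summary$coverage_pre <- mean(cp$present[, "pre"])
  summary$class_counts <- as.list(table(fit$class))
  summary$replicate_r2 <- lapply(
    replicate_correlation(counts, min_reads = cfg$min_reads_corr),
    function(m) round(m, 4))

  net <- .run_stage("network", quiet, {
    g <- build_graph(fit, mode = cfg$mode, codon_model = cfg$codon_model)
    sources <- rxxg_sources(g)
    ens <- if (cfg$target %in% igraph::V(g)$name && length(sources)) {
      shortest_path_ensemble(g, sources, cfg$target)
    } else {
      NULL
    }
    list(graph = g, sources = sources, ensemble = ens)
  })
  export_graph(net$graph, file.path(outdir, "network.graphml"))
  summary$graph <- list(n_nodes = igraph::vcount(net$graph),
                        n_edges = igraph::ecount(net$graph),
                        mode = cfg$mode, codon_model = cfg$codon_model)
  if (!is.null(net$ensemble) && net$ensemble$n_paths > 0) {
    ens <- net$ensemble
    reach <- cumulative_reach(ens, max_steps = cfg$max_steps)
    steps <- step_feature_fractions(ens)
    trav <- class_traversal(ens, net$graph)
    summary$paths <- list(
      n_sources = length(ens$sources), n_paths = ens$n_paths,
      max_steps = max(ens$dist[is.finite(ens$dist)], -Inf),
      cumulative_reach = as.list(reach), traversal_pct = as.list(trav))
    utils::write.table(
      data.frame(step = rownames(steps), steps, check.names = FALSE),
      file.path(outdir, "step_features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (cfg$shuffles > 0) {
      nd <- .run_stage("network", quiet, {
        shuffle_null(net$graph, ens$sources, cfg$target,
                     n_shuffles = cfg$shuffles,
                     seed = .stage_seed(cfg$seed, 14L))
      })
      summary$null <- list(n_shuffles = nd$n_shuffles,
                           observed = as.list(nd$observed),
                           null_mean = as.list(colMeans(nd$null)),
                           percentile = as.list(nd$percentile))
      utils::write.table(
        data.frame(shuffle = seq_len(nrow(nd$null)), nd$null),
        file.path(outdir, "null_traversal.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  clus <- .run_stage("cluster", quiet, {
    kd <- synthetic_kd_matrix(seed = .stage_seed(cfg$seed, 15L))
    list(kd = kd, clust = cluster_heatmap(kd, sentinel_cap = cfg$kd_cap))
  })
  write_kd_matrix(clus$kd, file.path(outdir, "kd_matrix_synthetic.csv"))
  ord <- clus$clust
  utils::write.table(
    ord$matrix[ord$row_order, ord$col_order],
    file.path(outdir, "kd_matrix_ordered.tsv"), sep = "\t", quote = FALSE)
  writeLines(c(merge_tree_newick(ord$row_tree),
               merge_tree_newick(ord$col_tree)),
             file.path(outdir, "kd_merge_trees.nwk"))
  summary$cluster <- list(row_order = ord$row_order, col_order = ord$col_order)

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config_hash = cfg_hash, config = unclass(cfg),
                   files = list.files(outdir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!quiet) message("pipeline complete: ", outdir)
  invisible(summary)
}
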