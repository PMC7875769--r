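# Pipeline orchestration: a validated configuration carrying every stage
# threshold at its canonical default, end-to-end runs over the synthetic
# compendium (simulate -> qc -> enhancers -> modules -> link -> gwas ->
# traits), a deterministic JSON manifest of every artifact, and per-locus
# reports.

#' Build and validate a pipeline configuration
#'
#' Carries the canonical analysis thresholds (activity signal 2, 100-bp
#' flank, link threshold 5/7, 5-kb pruning, 2.5-kb overlap radius, 0.25
#' cosine edge threshold) together with desk-scale run sizes (number of
#' catalog shuffles and marginal-preserving permutations) and a master seed
#' from which every stage derives its own RNG stream.
#'
#' @param seed master seed.
#' @param synth a [synth_config()] (defaults to `synth_config(seed)`).
#' @param k number of modules for clustering; `NULL` uses the generator's
#'   planted module count.
#' @param signal_threshold,flank_bp active-enhancer call parameters.
#' @param link_threshold keep cutoff for links (default `5/7`).
#' @param prune_window_bp,overlap_radius_bp GWAS distances.
#' @param n_shuffles empirical-FDR shuffles (default 100).
#' @param n_perm fixed-marginal permutation samples (default 10,000; runs
#'   at desk scale typically lower this).
#' @param edge_threshold trait-network cosine cutoff.
#' @param alpha BH significance level.
#' @param qc_swaps integer pair `c(sample, antibody)` swap counts planted
#'   in the QC stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, synth = NULL, k = NULL,
                            signal_threshold = 2, flank_bp = 100L,
                            link_threshold = 5 / 7,
                            prune_window_bp = 5000L,
                            overlap_radius_bp = 2500L,
                            n_shuffles = 100L, n_perm = 10000L,
                            edge_threshold = 0.25, alpha = 0.05,
                            qc_swaps = c(0L, 0L)) {
  cfg <- list(seed = as.integer(seed),
              synth = synth %||% synth_config(seed = seed),
              k = k, signal_threshold = signal_threshold,
              flank_bp = as.integer(flank_bp),
              link_threshold = link_threshold,
              prune_window_bp = as.integer(prune_window_bp),
              overlap_radius_bp = as.integer(overlap_radius_bp),
              n_shuffles = as.integer(n_shuffles),
              n_perm = as.integer(n_perm),
              edge_threshold = edge_threshold, alpha = alpha,
              qc_swaps = as.integer(qc_swaps))
  stopifnot(inherits(cfg$synth, "synth_config"),
            cfg$signal_threshold > 0, cfg$flank_bp >= 0,
            cfg$link_threshold > 0 && cfg$link_threshold < 1,
            cfg$prune_window_bp > 0, cfg$overlap_radius_bp > 0,
            cfg$n_shuffles >= 1, cfg$n_perm >= 1,
            cfg$edge_threshold >= 0 && cfg$edge_threshold <= 1,
            cfg$alpha > 0 && cfg$alpha < 1, length(cfg$qc_swaps) == 2)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file with any subset of [pipeline_config()]'s fields (the
#'   `synth` block maps to [synth_config()] arguments).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  synth <- if (!is.null(raw$synth))
    do.call(synth_config, raw$synth) else NULL
  raw$synth <- NULL
  do.call(pipeline_config, c(raw, list(synth = synth)))
}

record_stage <- function(manifest, stage, params, seed, inputs, outputs,
                         warnings = character(0)) {
  manifest$stages[[stage]] <- list(
    inputs = inputs, outputs = outputs,
    parameter_hash = object_md5(params), seed = seed,
    warnings = warnings
  )
  manifest
}

#' Run the full pipeline on a synthetic compendium
#'
#' Executes simulate, qc, enhancers, modules, link, gwas and traits in
#' dependency order, writing every artifact under `out_dir` and returning
#' a manifest that records, per stage, its inputs, outputs, parameter hash
#' and seed. The manifest (JSON) contains only deterministic fields, so a
#' rerun with an identical configuration reproduces it byte for byte;
#' wall-clock timings go to `run.log`. Failures abort with the failing
#' stage named.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the manifest (invisibly also written to `manifest.json`), with
#'   the in-memory stage results attached as attribute `results`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("pipeline start\n", file = log_path)
  manifest <- list(package = "enhancermap",
                   parameter_hash = object_md5(unclass(config)),
                   seed = config$seed, stages = list())
  results <- list()
  t0 <- Sys.time()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    cat(sprintf("stage %s done in %.1fs\n", name,
                as.numeric(Sys.time() - t0, units = "secs")),
        file = log_path, append = TRUE)
    res
  }

  # simulate
  sim_dir <- file.path(out_dir, "simulate")
  results$compendium <- stage("simulate", function()
    generate_compendium(config$synth, sim_dir))
  results$gwas_input <- stage("simulate", function()
    generate_gwas_catalog(config$synth, results$compendium))
  cat_path <- file.path(sim_dir, "gwas_catalog.tsv")
  data.table::fwrite(results$gwas_input$catalog, cat_path, sep = "\t")
  manifest <- record_stage(manifest, "simulate", config$synth, config$seed,
                           inputs = character(0),
                           outputs = sort(list.files(sim_dir)))

  # qc
  qc_dir <- file.path(out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  results$qc <- stage("qc", function() {
    qcc <- generate_qc_compendium(seed = config$seed)
    planted <- plant_swaps(qcc$observed, config$qc_swaps[1],
                           config$qc_swaps[2], seed = config$seed)
    metrics <- data.table::rbindlist(lapply(names(planted$tracks), function(id)
      c(list(track = id),
        qc_metrics(planted$tracks[[id]], qcc$imputed[[id]]))))
    flags <- rbind(detect_sample_swaps(planted$tracks, qcc$imputed),
                   detect_antibody_swaps(planted$tracks, qcc$imputed),
                   fill = TRUE)
    low <- flag_low_quality(stats::setNames(metrics$genomewide_correlation,
                                            metrics$track))
    list(metrics = metrics, flags = flags, low_quality = low,
         registry = planted$registry)
  })
  data.table::fwrite(results$qc$metrics, file.path(qc_dir, "qc_metrics.tsv"),
                     sep = "\t")
  data.table::fwrite(results$qc$flags, file.path(qc_dir, "flag_report.tsv"),
                     sep = "\t")
  manifest <- record_stage(manifest, "qc",
                           list(swaps = config$qc_swaps), config$seed,
                           inputs = character(0),
                           outputs = sort(list.files(qc_dir)))

  # enhancers
  enh_dir <- file.path(out_dir, "enhancers")
  dir.create(enh_dir, showWarnings = FALSE)
  comp <- results$compendium
  results$activity <- stage("enhancers", function()
    call_active_enhancers(comp$dhs, comp$segmentations, comp$tracks,
                          signal_threshold = config$signal_threshold,
                          flank_bp = config$flank_bp))
  act <- results$activity
  write_bed(act$elements, file.path(enh_dir, "active_enhancers.bed"))
  data.table::fwrite(data.table::as.data.table(act$A, keep.rownames = "id"),
                     file.path(enh_dir, "activity_matrix.tsv"), sep = "\t")
  manifest <- record_stage(manifest, "enhancers",
                           list(signal_threshold = config$signal_threshold,
                                flank_bp = config$flank_bp), config$seed,
                           inputs = "simulate", outputs = sort(list.files(enh_dir)))

  # modules
  mod_dir <- file.path(out_dir, "modules")
  dir.create(mod_dir, showWarnings = FALSE)
  k <- config$k %||% config$synth$n_modules
  results$modules <- stage("modules", function() {
    if (k > nrow(unique((act$A > 0) * 1)))
      stop("k = ", k, " exceeds the number of distinct enhancer rows")
    cluster_modules(act$A, k = k, seed = config$seed)
  })
  data.table::fwrite(data.table::data.table(
    element = names(results$modules$assignment),
    module = results$modules$assignment),
    file.path(mod_dir, "module_assignment.tsv"), sep = "\t")
  results$module_enrichment <- metadata_enrichment(results$modules,
                                                   comp$metadata)
  data.table::fwrite(results$module_enrichment,
                     file.path(mod_dir, "metadata_enrichment.tsv"), sep = "\t")
  manifest <- record_stage(manifest, "modules", list(k = k), config$seed,
                           inputs = "enhancers",
                           outputs = sort(list.files(mod_dir)))

  # link
  link_dir <- file.path(out_dir, "link")
  dir.create(link_dir, showWarnings = FALSE)
  results$links <- stage("link", function() {
    enh_elems <- if ("kind" %in% names(act$elements))
      act$elements[act$elements$kind == "enhancer", ] else act$elements
    cand <- candidate_correlations(comp$expression,
                                   list(H3K27ac = act$S), comp$tss,
                                   enh_elems)
    truth_keys <- paste(comp$truth$true_links$enhancer,
                        comp$truth$true_links$gene)
    pos <- cand[paste(cand$enhancer, cand$gene) %in% truth_keys, ]
    neg <- make_negatives(pos, comp$expression, list(H3K27ac = act$S),
                          comp$tss, seed = config$seed)
    clf <- train_link_classifier(pos, neg, seed = config$seed)
    pred <- predict_links(clf, cand, act$A, threshold = config$link_threshold)
    list(candidates = cand, classifier = clf, predictions = pred)
  })
  data.table::fwrite(results$links$predictions[results$links$predictions$kept, ],
                     file.path(link_dir, "kept_links.tsv"), sep = "\t")
  manifest <- record_stage(manifest, "link",
                           list(threshold = config$link_threshold),
                           config$seed, inputs = c("simulate", "enhancers"),
                           outputs = sort(list.files(link_dir)))

  # gwas
  gwas_dir <- file.path(out_dir, "gwas")
  dir.create(gwas_dir, showWarnings = FALSE)
  results$gwas <- stage("gwas", function() {
    pruned <- prune_catalog(results$gwas_input$catalog,
                            window_bp = config$prune_window_bp)
    sets <- per_sample_sets(act)
    flat <- flat_enrichment(pruned, sets, alpha = config$alpha,
                            radius_bp = config$overlap_radius_bp)
    fdr <- empirical_fdr(pruned, sets, n_shuffles = config$n_shuffles,
                         seed = config$seed, alpha = config$alpha,
                         radius_bp = config$overlap_radius_bp)
    tree <- build_tree(act)
    tenr <- tree_enrichment(pruned, tree, alpha = config$alpha,
                            radius_bp = config$overlap_radius_bp)
    rare <- rarefaction_curve(flat)
    list(pruned = pruned, flat = flat, fdr = fdr, tree = tree,
         tree_enrichment = tenr, rarefaction = rare)
  })
  data.table::fwrite(results$gwas$pruned,
                     file.path(gwas_dir, "pruned_catalog.tsv"), sep = "\t")
  data.table::fwrite(results$gwas$flat,
                     file.path(gwas_dir, "flat_enrichment.tsv"), sep = "\t")
  data.table::fwrite(results$gwas$tree_enrichment,
                     file.path(gwas_dir, "tree_enrichment.tsv"), sep = "\t")
  data.table::fwrite(results$gwas$rarefaction,
                     file.path(gwas_dir, "rarefaction.tsv"), sep = "\t")
  writeLines(tree_newick(results$gwas$tree),
             file.path(gwas_dir, "biosample_tree.nwk"))
  manifest <- record_stage(manifest, "gwas",
                           list(window = config$prune_window_bp,
                                radius = config$overlap_radius_bp,
                                shuffles = config$n_shuffles,
                                alpha = config$alpha),
                           config$seed, inputs = c("simulate", "enhancers"),
                           outputs = sort(list.files(gwas_dir)))

  # traits
  tr_dir <- file.path(out_dir, "traits")
  dir.create(tr_dir, showWarnings = FALSE)
  results$traits <- stage("traits", function() {
    labels <- assign_node_tissues(results$gwas$tree, comp$metadata)
    ttm <- tissue_trait_matrix(results$gwas$tree_enrichment, labels)
    cls <- suppressWarnings(classify_traits(ttm > 0))
    sim <- tissue_similarity(ttm > 0)
    net <- trait_network(ttm, edge_threshold = config$edge_threshold,
                         layout_seed = config$seed)
    gnet <- genetic_overlap_network(results$gwas$pruned)
    list(node_labels = labels, matrix = ttm, classes = cls,
         similarity = sim, network = net, genetic_network = gnet)
  })
  data.table::fwrite(data.table::as.data.table(results$traits$matrix,
                                               keep.rownames = "tissue"),
                     file.path(tr_dir, "tissue_trait_matrix.tsv"), sep = "\t")
  data.table::fwrite(results$traits$classes,
                     file.path(tr_dir, "trait_classes.tsv"), sep = "\t")
  data.table::fwrite(results$traits$network$edges,
                     file.path(tr_dir, "trait_network_edges.tsv"), sep = "\t")
  data.table::fwrite(results$traits$genetic_network,
                     file.path(tr_dir, "genetic_overlap_edges.tsv"), sep = "\t")
  manifest <- record_stage(manifest, "traits",
                           list(edge_threshold = config$edge_threshold),
                           config$seed, inputs = c("gwas", "simulate"),
                           outputs = sort(list.files(tr_dir)))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(manifest, "results") <- results
  invisible(manifest)
}

#' Per-biosample active-enhancer interval sets
#'
#' Splits an `activity_matrix` into one enhancer-interval table per
#' biosample (the annotation sets used by flat enrichment).
#'
#' @param activity an `activity_matrix`.
#' @return named list of data.tables (chrom, start, end, id).
#' @export
per_sample_sets <- function(activity) {
  stopifnot(inherits(activity, "activity_matrix"))
  stats::setNames(lapply(colnames(activity$A), function(s)
    activity$elements[activity$A[, s] > 0, ]), colnames(activity$A))
}

#' Per-locus report for a trait
#'
#' For each of the trait's lead SNPs, lists per top enriched tree node the
#' nearest active enhancer within the overlap radius (empty when none),
#' the genes linked from SNP-proximal enhancers in the top nodes, any link
#' in the locus present in at least half of the samples of the selected
#' tissue groups, and the mean H3K27ac signal of the enhancer across the
#' node's leaves.
#'
#' @param trait trait name.
#' @param pruned pruned catalog.
#' @param tree_enr [tree_enrichment()] table.
#' @param tree the `biosample_tree`.
#' @param activity the `activity_matrix` (provides intervals and signal).
#' @param links kept link predictions (enhancer, gene, biosample).
#' @param metadata biosample metadata (for the >= 50%-of-group rule).
#' @param groups tissue groups whose recurrent links to include (default
#'   none).
#' @param top_nodes number of top enriched nodes (default 3).
#' @param radius_bp nearest-enhancer radius (default 2,500).
#' @return data.table, one row per (lead SNP, node).
#' @export
locus_report <- function(trait, pruned, tree_enr, tree, activity, links,
                         metadata, groups = character(0), top_nodes = 3L,
                         radius_bp = 2500L) {
  # plain-vector masks: `trait` is both an argument and a column name, and
  # data.table's i-scope would resolve it to the column
  te <- data.table::as.data.table(tree_enr)
  te_keep <- which(te[["trait"]] == trait)
  if (length(te_keep) == 0L) stop("trait absent from enrichments: ", trait)
  te <- te[te_keep, ]
  te <- te[order(te$p_hyper), ]
  nodes <- utils::head(unique(te$node), top_nodes)
  cat_dt <- data.table::as.data.table(pruned)
  snps <- cat_dt[which(cat_dt[["trait"]] == trait), ]
  links <- data.table::as.data.table(links)
  metadata <- data.table::as.data.table(metadata)

  # links present in >= 50% of the samples of each selected group
  recurrent <- character(0)
  for (g in groups) {
    gs <- metadata$sample[metadata$group == g]
    lk <- links[links$biosample %in% gs, ]
    cnt <- lk[, list(nshare = data.table::uniqueN(biosample)),
              by = list(enhancer, gene)]
    recurrent <- c(recurrent,
                   paste(cnt$enhancer[cnt$nshare >= length(gs) / 2],
                         cnt$gene[cnt$nshare >= length(gs) / 2]))
  }
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (v in nodes) {
      rows <- tree$nodes[[v]]$tested
      enh <- activity$elements[rows, ]
      ov <- snp_enhancer_overlap(snps[i, ], enh, radius_bp)
      if (nrow(ov) == 0L) {
        out[[length(out) + 1L]] <- data.table::data.table(
          trait = trait, snp_pos = snps$pos[i], chrom = snps$chrom[i],
          node = v, enhancer = NA_character_, note = "no enhancer within radius",
          linked_genes = "", mean_signal = NA_real_)
        next
      }
      nearest <- ov[which.min(abs(ov$distance)), ]
      direct <- links$gene[links$enhancer == nearest$enhancer & links$kept]
      rec_genes <- sub("^\\S+ ", "",
                       recurrent[grepl(paste0("^", nearest$enhancer, " "),
                                       recurrent)])
      leaves <- tree$nodes[[v]]$leaves
      out[[length(out) + 1L]] <- data.table::data.table(
        trait = trait, snp_pos = snps$pos[i], chrom = snps$chrom[i],
        node = v, enhancer = nearest$enhancer, note = "",
        linked_genes = paste(unique(c(direct, rec_genes)), collapse = ","),
        mean_signal = mean(activity$S[nearest$enhancer,
                                      tree$labels[leaves]]))
    }
  }
  data.table::rbindlist(out)
}
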