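# Seeded synthetic epigenomic compendium with planted ground truth: enhancer
# modules with tissue-specific activity, enhancer-gene links driving an
# expression matrix, a GWAS catalog with trait-tissue associations, and
# label swaps for the QC detectors. Every downstream stage of the pipeline
# has a known answer on these data.

#' Chromatin-state mnemonics of the 18-state model used by the pipeline
#'
#' Enhancer states are E7-E11 and E15; promoter states are E1-E4 and E14;
#' E18 is quiescent background.
#' @export
ENHANCER_STATES <- c("E7", "E8", "E9", "E10", "E11", "E15")

#' @rdname ENHANCER_STATES
#' @export
PROMOTER_STATES <- c("E1", "E2", "E3", "E4", "E14")

ALL_STATES <- paste0("E", 1:18)

TISSUE_NAMES <- c("brain", "heart", "lung", "liver", "kidney", "muscle",
                  "blood", "skin", "intestine", "pancreas", "spleen",
                  "thymus", "adipose", "ovary", "testis", "stomach")

#' Synthetic-compendium configuration
#'
#' Bundles and validates every knob of the generator. Defaults describe the
#' package's reference desk-scale compendium: a 6-Mb genome in 200-bp bins,
#' 40 biosamples in 5 tissue groups, 6 planted enhancer modules of 200
#' enhancers each (one of them broadly active), module membership expressed
#' in a biosample with probability 0.9 and leaked into foreign biosamples
#' with probability 0.02.
#'
#' @param seed master seed; all artifact-class RNG streams derive from it.
#' @param n_chromosomes,chrom_length_bp,bin_bp genome declaration;
#'   `bin_bp` must divide `chrom_length_bp`.
#' @param n_tissue_groups,samples_per_group biosample design.
#' @param n_modules,enhancers_per_module planted module structure;
#'   `n_modules >= n_tissue_groups`.
#' @param module_activity_prob probability that an enhancer of a module is
#'   active in a biosample of one of the module's tissue groups.
#' @param leak_prob probability of spurious activity outside the module's
#'   groups.
#' @param broad_module_fraction fraction of modules active in at least 77%
#'   of tissue groups (the "broadly active" block).
#' @param n_genes,links_per_gene,link_window_bp,expression_noise_sd planted
#'   enhancer-gene links: each gene is driven by a weighted sum of the mean
#'   H3K27ac signal of its linked enhancers (all within `link_window_bp` of
#'   the TSS) plus Gaussian noise.
#' @param n_traits,lead_snps_per_trait,planted_snp_fraction,background_snp_count
#'   GWAS catalog design: each trait is assigned a tissue group and
#'   `planted_snp_fraction` of its lead SNPs are placed within 2.5 kb of
#'   midpoints of enhancers active in that group; the rest (and any
#'   background SNPs) are uniform.
#' @param n_swapped_tracks number of track-label swaps planted by default
#'   when [plant_swaps()] is driven from the pipeline.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chromosomes = 3L,
                         chrom_length_bp = 2000000L,
                         bin_bp = 200L,
                         n_tissue_groups = 5L,
                         samples_per_group = 8L,
                         n_modules = 6L,
                         enhancers_per_module = 200L,
                         module_activity_prob = 0.9,
                         leak_prob = 0.02,
                         broad_module_fraction = 1 / 6,
                         n_genes = 60L,
                         links_per_gene = 2L,
                         link_window_bp = 1000000L,
                         expression_noise_sd = 0.5,
                         n_traits = 10L,
                         lead_snps_per_trait = 30L,
                         planted_snp_fraction = 0.8,
                         background_snp_count = 0L,
                         n_swapped_tracks = 0L) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp), bin_bp = as.integer(bin_bp),
    n_tissue_groups = as.integer(n_tissue_groups),
    samples_per_group = as.integer(samples_per_group),
    n_modules = as.integer(n_modules),
    enhancers_per_module = as.integer(enhancers_per_module),
    module_activity_prob = module_activity_prob, leak_prob = leak_prob,
    broad_module_fraction = broad_module_fraction,
    n_genes = as.integer(n_genes), links_per_gene = as.integer(links_per_gene),
    link_window_bp = as.integer(link_window_bp),
    expression_noise_sd = expression_noise_sd,
    n_traits = as.integer(n_traits),
    lead_snps_per_trait = as.integer(lead_snps_per_trait),
    planted_snp_fraction = planted_snp_fraction,
    background_snp_count = as.integer(background_snp_count),
    n_swapped_tracks = as.integer(n_swapped_tracks)
  )
  probs <- c(cfg$module_activity_prob, cfg$leak_prob,
             cfg$broad_module_fraction, cfg$planted_snp_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$chrom_length_bp %% cfg$bin_bp != 0L)
    stop("bin_bp must divide chrom_length_bp")
  if (cfg$n_modules < cfg$n_tissue_groups)
    stop("n_modules must be >= n_tissue_groups")
  if (cfg$expression_noise_sd < 0) stop("expression_noise_sd must be >= 0")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic epigenomic compendium
#'
#' Builds biosample metadata, per-sample 18-state segmentations, per-sample
#' H3K27ac signal tracks, a DHS index, gene TSSs, an expression matrix and
#' the planted ground truth. Enhancer elements occupy single bins spaced at
#' least three bins apart so their +/-100-bp flanks never collide. In a
#' biosample where an enhancer is active, its bin carries one of the six
#' enhancer-state mnemonics and a signal plateau of `2 + Gamma(2, 1.5)` over
#' the bin and both flanking bins; everywhere else, signal is
#' `Exponential(mean 0.5)` background. Identical configs (including seed)
#' yield byte-identical emitted files.
#'
#' @param config a [synth_config()].
#' @param out_dir optional directory; when given, all artifacts are written
#'   there as plain-text BED / bedGraph / TSV.
#' @return a list of class `synth_compendium` with elements `config`,
#'   `genome`, `metadata`, `dhs`, `segmentations`, `tracks`, `expression`,
#'   `tss` and `truth` (module assignment, module activity, activity matrix,
#'   signal matrix, true links, states).
#' @export
generate_compendium <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  bins_per_chrom <- cfg$chrom_length_bp %/% cfg$bin_bp
  chroms <- paste0("chrS", seq_len(cfg$n_chromosomes))
  genome <- data.table::data.table(chrom = chroms,
                                   length_bp = cfg$chrom_length_bp)
  n_enh <- cfg$n_modules * cfg$enhancers_per_module
  n_elem <- n_enh + cfg$n_genes

  # --- layout stream: placement, metadata, modules, links -------------------
  set.seed(derive_seed(cfg$seed, "layout"))

  # slots of 4 bins guarantee >= 3-bin spacing between planted elements
  slots_per_chrom <- bins_per_chrom %/% 4L
  if (n_elem > slots_per_chrom * cfg$n_chromosomes)
    stop("n_modules * enhancers_per_module + n_genes exceeds available bins")
  slot_ids <- sample.int(slots_per_chrom * cfg$n_chromosomes, n_elem)
  slot_chrom <- (slot_ids - 1L) %/% slots_per_chrom + 1L
  slot_bin <- ((slot_ids - 1L) %% slots_per_chrom) * 4L + 1L  # 0-based bin
  ord <- order(slot_chrom, slot_bin)
  elem <- data.table::data.table(
    chrom = chroms[slot_chrom[ord]],
    bin = slot_bin[ord],
    start = slot_bin[ord] * cfg$bin_bp
  )
  elem[, end := start + cfg$bin_bp]
  elem[, id := sprintf("dhs_%05d", .I)]
  is_gene_slot <- rep(FALSE, n_elem)
  is_gene_slot[sample.int(n_elem, cfg$n_genes)] <- TRUE
  elem[, kind := ifelse(is_gene_slot, "promoter", "enhancer")]

  groups <- TISSUE_NAMES[seq_len(cfg$n_tissue_groups)]
  if (cfg$n_tissue_groups > length(TISSUE_NAMES))
    groups <- c(TISSUE_NAMES,
                sprintf("tissue%02d",
                        seq_len(cfg$n_tissue_groups - length(TISSUE_NAMES))))
  n_samples <- cfg$n_tissue_groups * cfg$samples_per_group
  metadata <- data.table::data.table(
    sample = sprintf("BSS%03d", seq_len(n_samples)),
    group = rep(groups, each = cfg$samples_per_group),
    life_stage = sample(c("adult", "embryonic"), n_samples, replace = TRUE),
    sex = sample(c("female", "male"), n_samples, replace = TRUE),
    type = sample(c("tissue", "primary_cell", "cell_line"), n_samples,
                  replace = TRUE)
  )

  # module -> tissue-group map: broad modules span >= 77% of groups,
  # the rest are tissue-specific, assigned round-robin
  n_broad <- round(cfg$broad_module_fraction * cfg$n_modules)
  n_spec <- cfg$n_modules - n_broad
  if (n_spec < cfg$n_tissue_groups && n_spec > 0)
    warning("fewer specific modules than tissue groups; some groups lack one")
  broad_size <- ceiling(0.77 * cfg$n_tissue_groups)
  module_groups <- vector("list", cfg$n_modules)
  for (m in seq_len(cfg$n_modules)) {
    module_groups[[m]] <- if (m <= n_spec) {
      groups[(m - 1L) %% cfg$n_tissue_groups + 1L]
    } else {
      sort(sample(groups, broad_size))
    }
  }
  names(module_groups) <- sprintf("module%02d", seq_len(cfg$n_modules))
  enh_idx <- which(elem$kind == "enhancer")
  module_assignment <- sample(rep(seq_len(cfg$n_modules),
                                  cfg$enhancers_per_module))
  names(module_assignment) <- elem$id[enh_idx]
  module_activity <- lapply(module_groups, function(gs)
    metadata$sample[metadata$group %in% gs])

  # planted enhancer-gene links
  gene_idx <- which(elem$kind == "promoter")
  tss <- data.table::data.table(
    gene = sprintf("gene%04d", seq_along(gene_idx)),
    chrom = elem$chrom[gene_idx],
    pos = elem$start[gene_idx],
    dhs_id = elem$id[gene_idx]
  )
  links <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    near <- enh_idx[elem$chrom[enh_idx] == tss$chrom[g] &
                    abs(elem$start[enh_idx] - tss$pos[g]) <= cfg$link_window_bp]
    if (length(near) < cfg$links_per_gene)
      stop("gene ", tss$gene[g], " has too few enhancers within the window")
    mods <- module_assignment[elem$id[near]]
    umods <- unique(mods)
    host_mod <- umods[sample.int(length(umods), 1L)]
    pool <- near[mods == host_mod]
    if (length(pool) < cfg$links_per_gene) pool <- near
    pick <- pool[sample.int(length(pool), cfg$links_per_gene)]
    links[[g]] <- data.table::data.table(
      gene = tss$gene[g], enhancer = elem$id[pick],
      module = module_assignment[elem$id[pick]],
      weight = stats::runif(cfg$links_per_gene, 0.5, 1.5)
    )
  }
  true_links <- data.table::rbindlist(links)
  true_links[, samples := lapply(module, function(m)
    module_activity[[m]])]

  # --- signal stream: activity draws, plateau heights, background -----------
  set.seed(derive_seed(cfg$seed, "signal"))
  in_module_sample <- matrix(FALSE, n_enh, n_samples,
                             dimnames = list(elem$id[enh_idx],
                                             metadata$sample))
  for (m in seq_len(cfg$n_modules))
    in_module_sample[module_assignment == m,
                     metadata$sample %in% module_activity[[m]]] <- TRUE
  p_active <- ifelse(in_module_sample, cfg$module_activity_prob, cfg$leak_prob)
  activity <- matrix(stats::runif(length(p_active)) < p_active,
                     n_enh, n_samples, dimnames = dimnames(in_module_sample))
  plateau <- matrix(2 + stats::rgamma(n_enh * n_samples, shape = 2,
                                      scale = 1.5),
                    n_enh, n_samples, dimnames = dimnames(in_module_sample))

  # promoter bins are active (promoter state + plateau) in samples where any
  # linked enhancer is active, so elements classify cleanly downstream
  prom_active <- matrix(FALSE, cfg$n_genes, n_samples,
                        dimnames = list(elem$id[gene_idx], metadata$sample))
  for (g in seq_len(cfg$n_genes)) {
    le <- true_links$enhancer[true_links$gene == tss$gene[g]]
    prom_active[g, ] <- colSums(activity[le, , drop = FALSE]) > 0
  }
  prom_plateau <- matrix(2 + stats::rgamma(cfg$n_genes * n_samples, 2,
                                           scale = 1.5),
                         cfg$n_genes, n_samples,
                         dimnames = dimnames(prom_active))

  tracks <- vector("list", n_samples)
  names(tracks) <- metadata$sample
  S_all <- matrix(NA_real_, n_elem, n_samples,
                  dimnames = list(elem$id, metadata$sample))
  elem_chrom_i <- match(elem$chrom, chroms)
  for (s in seq_len(n_samples)) {
    sig <- lapply(chroms, function(ch)
      stats::rexp(bins_per_chrom, rate = 2))
    names(sig) <- chroms
    act_e <- activity[, s]
    act_p <- prom_active[, s]
    val <- numeric(n_elem)
    val[enh_idx] <- plateau[, s]
    val[gene_idx] <- prom_plateau[, s]
    on <- logical(n_elem)
    on[enh_idx] <- act_e
    on[gene_idx] <- act_p
    for (i in which(on)) {
      b <- elem$bin[i] + 1L  # 1-based bin index
      sig[[elem_chrom_i[i]]][(b - 1L):(b + 1L)] <- val[i]
    }
    # element-level mean over DHS +/- 100 bp: plateau when on, else the
    # overlap-weighted background mean ((half left + mid + half right) / 2)
    sm <- numeric(n_elem)
    for (i in seq_len(n_elem)) {
      b <- elem$bin[i] + 1L
      v <- sig[[elem_chrom_i[i]]]
      sm[i] <- (0.5 * v[b - 1L] + v[b] + 0.5 * v[b + 1L]) / 2
    }
    S_all[, s] <- sm
    tracks[[s]] <- signal_track(metadata$sample[s], "H3K27ac", sig,
                                cfg$bin_bp)
  }

  # --- states stream: per-active-occurrence enhancer mnemonics --------------
  set.seed(derive_seed(cfg$seed, "states"))
  state_codes <- matrix(NA_character_, n_elem, n_samples,
                        dimnames = list(elem$id, metadata$sample))
  enh_states <- state_codes[enh_idx, , drop = FALSE]
  enh_states[activity] <- sample(ENHANCER_STATES, sum(activity),
                                 replace = TRUE)
  state_codes[enh_idx, ] <- enh_states
  prom_states <- state_codes[gene_idx, , drop = FALSE]
  prom_states[prom_active] <- "E1"
  state_codes[gene_idx, ] <- prom_states
  segmentations <- vector("list", n_samples)
  names(segmentations) <- metadata$sample
  for (s in seq_len(n_samples)) {
    st <- lapply(chroms, function(ch) rep("E18", bins_per_chrom))
    names(st) <- chroms
    for (i in seq_len(n_elem)) {
      code <- state_codes[i, s]
      if (!is.na(code)) st[[elem_chrom_i[i]]][elem$bin[i] + 1L] <- code
    }
    segmentations[[s]] <- st
  }

  # --- expression stream ----------------------------------------------------
  set.seed(derive_seed(cfg$seed, "expression"))
  expression <- matrix(0, cfg$n_genes, n_samples,
                       dimnames = list(tss$gene, metadata$sample))
  for (g in seq_len(cfg$n_genes)) {
    lk <- true_links[true_links$gene == tss$gene[g], ]
    expression[g, ] <- colSums(S_all[lk$enhancer, , drop = FALSE] * lk$weight)
  }
  expression <- expression +
    matrix(stats::rnorm(length(expression), 0, cfg$expression_noise_sd),
           nrow(expression))

  truth <- list(
    module_assignment = module_assignment,
    module_groups = module_groups,
    module_activity = module_activity,
    activity = activity,
    signal = S_all,
    true_links = true_links,
    states = state_codes
  )
  comp <- structure(
    list(config = cfg, genome = genome, metadata = metadata,
         dhs = elem[, c("chrom", "start", "end", "id", "kind")],
         segmentations = segmentations, tracks = tracks,
         expression = expression, tss = tss, truth = truth),
    class = "synth_compendium"
  )
  if (!is.null(out_dir)) write_compendium(comp, out_dir)
  comp
}

#' Write a synthetic compendium to disk as plain-text artifacts
#'
#' @param comp a `synth_compendium`.
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths written.
#' @export
write_compendium <- function(comp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metadata = file.path(dir, "metadata.tsv"),
    dhs = file.path(dir, "dhs_index.bed"),
    tss = file.path(dir, "gene_tss.bed"),
    expression = file.path(dir, "expression.tsv")
  )
  data.table::fwrite(comp$metadata, paths["metadata"], sep = "\t")
  write_bed(comp$dhs, paths["dhs"])
  write_bed(data.table::data.table(chrom = comp$tss$chrom,
                                   start = comp$tss$pos,
                                   end = comp$tss$pos + 1L,
                                   id = comp$tss$gene), paths["tss"])
  expr <- data.table::as.data.table(comp$expression, keep.rownames = "gene")
  data.table::fwrite(expr, paths["expression"], sep = "\t")
  for (s in names(comp$segmentations)) {
    p <- file.path(dir, sprintf("segmentation_%s.bed", s))
    write_segmentation(comp$segmentations[[s]], comp$config$bin_bp, p)
    paths[paste0("seg_", s)] <- p
  }
  for (s in names(comp$tracks)) {
    p <- file.path(dir, sprintf("%s_H3K27ac.bedGraph", s))
    write_bedgraph(comp$tracks[[s]], p)
    paths[paste0("track_", s)] <- p
  }
  invisible(paths)
}

#' Generate a synthetic GWAS catalog with planted trait-tissue associations
#'
#' Each trait is a single study (one PubMed id) of `lead_snps_per_trait`
#' associations with log-uniform p-values in \[1e-30, 5e-8\] and a sample
#' size of at least 10,000. A `planted_snp_fraction` of a trait's SNPs are
#' placed within 2.5 kb of the midpoints of enhancers active in the trait's
#' tissue group; the remainder (and optional background associations) are
#' uniform over the genome.
#'
#' @param config the [synth_config()] used for the compendium.
#' @param comp the generated `synth_compendium` (provides enhancer positions
#'   and module activity).
#' @return a list with `catalog` (data.table: trait, pubmed_id, chrom, pos
#'   1-based, pvalue, sample_size), `trait_tissue` (trait -> tissue group)
#'   and `planted_snps` (per-association host enhancer id, NA for
#'   background).
#' @export
generate_gwas_catalog <- function(config, comp) {
  stopifnot(inherits(comp, "synth_compendium"))
  cfg <- config
  set.seed(derive_seed(cfg$seed, "catalog"))
  groups <- unique(comp$metadata$group)
  traits <- sprintf("trait%02d", seq_len(cfg$n_traits))
  trait_tissue <- groups[(seq_len(cfg$n_traits) - 1L) %% length(groups) + 1L]
  names(trait_tissue) <- traits

  enh <- comp$dhs[comp$dhs$kind == "enhancer", ]
  mid1 <- (enh$start + enh$end) %/% 2L + 1L  # 1-based midpoint
  # enhancers active in a tissue group = members of modules whose planted
  # group set contains it (ground-truth activity, not leak-contaminated calls)
  rows <- vector("list", cfg$n_traits)
  hosts <- vector("list", cfg$n_traits)
  for (t in seq_len(cfg$n_traits)) {
    g <- trait_tissue[t]
    mods <- which(vapply(comp$truth$module_groups, function(x) g %in% x, TRUE))
    active_enh <- which(enh$id %in% names(comp$truth$module_assignment)[
      comp$truth$module_assignment %in% mods])
    if (length(active_enh) == 0L)
      stop("tissue group ", g, " has no active enhancers to host SNPs")
    n <- cfg$lead_snps_per_trait
    n_planted <- round(cfg$planted_snp_fraction * n)
    host <- rep(NA_character_, n)
    chrom <- character(n)
    pos <- integer(n)
    if (n_planted > 0) {
      hi <- active_enh[sample.int(length(active_enh), n_planted,
                                  replace = TRUE)]
      host[seq_len(n_planted)] <- enh$id[hi]
      chrom[seq_len(n_planted)] <- enh$chrom[hi]
      pos[seq_len(n_planted)] <- pmin(
        pmax(mid1[hi] + sample(-2500:2500, n_planted, replace = TRUE), 1L),
        cfg$chrom_length_bp)
    }
    if (n_planted < n) {
      bg <- (n_planted + 1L):n
      chrom[bg] <- paste0("chrS", sample.int(cfg$n_chromosomes, length(bg),
                                             replace = TRUE))
      pos[bg] <- sample.int(cfg$chrom_length_bp, length(bg), replace = TRUE)
    }
    rows[[t]] <- data.table::data.table(
      trait = traits[t], pubmed_id = 30000000L + t, chrom = chrom, pos = pos,
      pvalue = 10^stats::runif(n, -30, log10(5e-8)),
      sample_size = 10000L + sample.int(90000L, 1L)
    )
    hosts[[t]] <- host
  }
  catalog <- data.table::rbindlist(rows)
  planted <- unlist(hosts)
  if (cfg$background_snp_count > 0) {
    nb <- cfg$background_snp_count
    bg <- data.table::data.table(
      trait = "background", pubmed_id = 29999999L,
      chrom = paste0("chrS", sample.int(cfg$n_chromosomes, nb, replace = TRUE)),
      pos = sample.int(cfg$chrom_length_bp, nb, replace = TRUE),
      pvalue = 10^stats::runif(nb, -30, log10(5e-8)),
      sample_size = 10000L + sample.int(90000L, 1L)
    )
    catalog <- rbind(catalog, bg)
    planted <- c(planted, rep(NA_character_, nb))
  }
  list(catalog = catalog, trait_tissue = trait_tissue,
       planted_snps = planted)
}

#' Plant sample- and antibody-label swaps in a track collection
#'
#' Exchanges the contents of randomly chosen track pairs: a *sample swap*
#' exchanges two same-mark tracks of different biosamples; an *antibody
#' swap* exchanges two marks of the same biosample. The returned registry
#' records the planted truth for detector evaluation. Swapped tracks are
#' never reused across swaps.
#'
#' @param tracks named list of [signal_track()]s (names `sample.mark`).
#' @param n_sample_swaps,n_antibody_swaps number of pairs of each kind.
#' @param seed RNG seed.
#' @return list with `tracks` (modified collection) and `registry`
#'   (data.table: kind, track_a, track_b).
#' @export
plant_swaps <- function(tracks, n_sample_swaps = 0L, n_antibody_swaps = 0L,
                        seed = 1L) {
  info <- data.table::data.table(
    id = names(tracks),
    sample = vapply(tracks, `[[`, "", "sample"),
    mark = vapply(tracks, `[[`, "", "mark")
  )
  set.seed(derive_seed(seed, "swaps"))
  used <- character(0)
  used_marks <- character(0)  # sample swaps spread across distinct marks
  reg <- list()
  pick_pair <- function(kind) {
    free <- info[!info$id %in% used, ]
    if (kind == "sample") {
      marks <- names(which(table(free$mark) >= 2))
      fresh <- setdiff(marks, used_marks)
      if (length(fresh)) marks <- fresh
      if (length(marks) == 0L) stop("not enough free track pairs to swap")
      m <- marks[sample.int(length(marks), 1L)]
      used_marks <<- c(used_marks, m)
      cand <- free$id[free$mark == m]
    } else {
      samps <- names(which(table(free$sample) >= 2))
      if (length(samps) == 0L) stop("not enough free track pairs to swap")
      s <- samps[sample.int(length(samps), 1L)]
      cand <- free$id[free$sample == s]
    }
    sample(cand, 2L)
  }
  do_swap <- function(kind, n) {
    for (i in seq_len(n)) {
      pr <- pick_pair(kind)
      a <- tracks[[pr[1]]]; b <- tracks[[pr[2]]]
      tmp <- a$signal; a$signal <- b$signal; b$signal <- tmp
      tracks[[pr[1]]] <<- a
      tracks[[pr[2]]] <<- b
      used <<- c(used, pr)
      reg[[length(reg) + 1L]] <<- data.table::data.table(
        kind = paste0(kind, "_swap"), track_a = pr[1], track_b = pr[2])
    }
  }
  do_swap("sample", n_sample_swaps)
  do_swap("antibody", n_antibody_swaps)
  registry <- if (length(reg)) data.table::rbindlist(reg) else
    data.table::data.table(kind = character(0), track_a = character(0),
                           track_b = character(0))
  list(tracks = tracks, registry = registry)
}

#' Generate a synthetic observed/imputed track compendium for QC testing
#'
#' Emulates a multi-mark compendium in which each track is an additive
#' mixture of a mark archetype, a tissue-group profile and a
#' biosample-private profile (all Gamma-distributed over bins), with
#' independent Gaussian noise added to the observed and imputed copies.
#' The mixture weights make the own-sample observed/imputed correlation
#' clearly larger than any cross-sample correlation, which is what the
#' swap detectors exploit.
#'
#' @param seed RNG seed.
#' @param n_groups,samples_per_group biosample design.
#' @param marks character vector of assay names.
#' @param n_bins,bin_bp single synthetic chromosome declaration.
#' @param w_mark,w_group,w_sample mixture weights.
#' @param noise_sd observed-track noise (imputed tracks get half of it).
#' @return list with `observed` and `imputed` (named lists of
#'   [signal_track()]s, names `sample.mark`) and `metadata`.
#' @export
generate_qc_compendium <- function(seed = 1L, n_groups = 8L,
                                   samples_per_group = 5L,
                                   marks = c("H3K27ac", "H3K4me1", "H3K4me3",
                                             "H3K9me3", "H3K36me3"),
                                   n_bins = 2000L, bin_bp = 200L,
                                   w_mark = 0.55, w_group = 0.25,
                                   w_sample = 0.2, noise_sd = 0.08) {
  set.seed(derive_seed(seed, "qc"))
  n_samples <- n_groups * samples_per_group
  samples <- sprintf("s%02d", seq_len(n_samples))
  group_of <- rep(seq_len(n_groups), each = samples_per_group)
  M <- matrix(stats::rgamma(n_bins * length(marks), 2, 1), n_bins)
  G <- matrix(stats::rgamma(n_bins * n_groups, 2, 1), n_bins)
  C <- matrix(stats::rgamma(n_bins * n_samples, 2, 1), n_bins)
  observed <- list(); imputed <- list()
  for (s in seq_len(n_samples)) {
    for (m in seq_along(marks)) {
      core <- w_mark * M[, m] + w_group * G[, group_of[s]] + w_sample * C[, s]
      id <- paste(samples[s], marks[m], sep = ".")
      observed[[id]] <- signal_track(
        samples[s], marks[m],
        stats::setNames(list(pmax(core + stats::rnorm(n_bins, 0, noise_sd),
                                  0)), "chrS1"), bin_bp)
      imputed[[id]] <- signal_track(
        samples[s], marks[m],
        stats::setNames(list(pmax(core + stats::rnorm(n_bins, 0,
                                                      noise_sd / 2), 0)),
                        "chrS1"), bin_bp)
    }
  }
  metadata <- data.table::data.table(sample = samples,
                                     group = sprintf("g%02d", group_of))
  list(observed = observed, imputed = imputed, metadata = metadata)
}
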