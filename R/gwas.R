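# GWAS catalog pruning and hypergeometric enrichment: greedy 5-kb pruning
# with HLA removal and power filters, the 2.5-kb midpoint overlap rule,
# flat enrichments with BH correction, trait-shuffle empirical FDR, the
# complete-linkage Jaccard biosample tree with consensus enhancer sets,
# node-level enrichment, and greedy rarefaction curves.

#' Prune a GWAS catalog
#'
#' Associations in the HLA locus are removed first; then, within each study
#' (trait + PubMed id), associations are ranked by increasing p-value and a
#' SNP is kept iff it lies more than `window_bp` from every previously kept
#' SNP on the same chromosome. Finally, studies with sample size below
#' `min_cases` or fewer than `min_snps` kept SNPs are dropped entirely.
#'
#' @param catalog data.frame: trait, pubmed_id, chrom, pos (1-based),
#'   pvalue, sample_size.
#' @param window_bp pruning distance (default 5,000).
#' @param hla_chrom,hla_range HLA interval removed up front (defaults
#'   chr6:29,691,116-33,054,976, inclusive; only applies to positions on
#'   `hla_chrom`).
#' @param min_cases,min_snps study-level power filters (defaults 10,000 and
#'   10).
#' @return the pruned catalog (same columns).
#' @export
prune_catalog <- function(catalog, window_bp = 5000L,
                          hla_chrom = "chr6",
                          hla_range = c(29691116L, 33054976L),
                          min_cases = 10000L, min_snps = 10L) {
  dt <- data.table::as.data.table(catalog)
  need <- c("trait", "pubmed_id", "chrom", "pos", "pvalue", "sample_size")
  stopifnot(all(need %in% names(dt)))
  if (!is.numeric(dt$pos) || any(is.na(dt$pos)) || any(dt$pos < 1))
    stop("malformed positions")
  dt <- dt[!(dt$chrom == hla_chrom & dt$pos >= hla_range[1] &
               dt$pos <= hla_range[2]), ]
  dt[, study := paste(trait, pubmed_id, sep = "|")]
  kept <- vector("list", length(unique(dt$study)))
  names(kept) <- unique(dt$study)
  for (st in unique(dt$study)) {
    d <- dt[dt$study == st, ]
    d <- d[order(d$pvalue, d$chrom, d$pos), ]
    keep <- logical(nrow(d))
    kept_pos <- split(numeric(0), character(0))
    for (i in seq_len(nrow(d))) {
      ch <- d$chrom[i]
      prev <- kept_pos[[ch]]
      if (is.null(prev) || all(abs(d$pos[i] - prev) > window_bp)) {
        keep[i] <- TRUE
        kept_pos[[ch]] <- c(prev, d$pos[i])
      }
    }
    kept[[st]] <- d[keep, ]
  }
  out <- data.table::rbindlist(kept)
  if (nrow(out)) {
    sizes <- out[, list(n_kept = .N, size = max(sample_size)), by = study]
    good <- sizes$study[sizes$n_kept >= min_snps & sizes$size >= min_cases]
    out <- out[out$study %in% good, ]
  }
  out[, study := NULL]
  out[]
}

#' SNP-enhancer overlap by the midpoint rule
#'
#' A SNP hits an enhancer iff it lies on the same chromosome within
#' `radius_bp` of the enhancer midpoint, inclusive. Midpoints of 0-based
#' half-open intervals are converted to 1-based coordinates before
#' comparison with the 1-based SNP positions.
#'
#' @param snps data.frame with `chrom`, `pos` (1-based).
#' @param enhancers data.frame with `chrom`, `start`, `end`, `id`.
#' @param radius_bp overlap radius (default 2,500).
#' @return data.table of hits: snp row index, chrom, pos, enhancer id,
#'   distance.
#' @export
snp_enhancer_overlap <- function(snps, enhancers, radius_bp = 2500L) {
  snps <- data.table::as.data.table(snps)
  enh <- data.table::as.data.table(enhancers)
  mid1 <- (enh$start + enh$end) %/% 2L + 1L
  win <- data.table::data.table(chrom = enh$chrom, s0 = mid1 - radius_bp,
                                s1 = mid1 + radius_bp, enhancer = enh$id,
                                mid1 = mid1)
  data.table::setkey(win, chrom, s0, s1)
  q <- data.table::data.table(chrom = snps$chrom, s0 = snps$pos,
                              s1 = snps$pos, snp = seq_len(nrow(snps)),
                              pos = snps$pos)
  ov <- data.table::foverlaps(q, win, type = "within", nomatch = NULL)
  data.table::data.table(snp = ov$snp, chrom = ov$chrom, pos = ov$pos,
                         enhancer = ov$enhancer,
                         distance = ov$pos - ov$mid1)
}

# Unique catalog SNP table + per-association index into it.
unique_snp_index <- function(catalog) {
  dt <- data.table::as.data.table(catalog)
  usnp <- unique(dt[, list(chrom, pos)])
  dt[, usnp_idx := match(paste(chrom, pos), paste(usnp$chrom, usnp$pos))]
  list(usnp = usnp, assoc = dt)
}

# Logical matrix: unique SNP x annotation set hit indicator.
snp_set_hit_matrix <- function(usnp, sets, radius_bp) {
  H <- matrix(FALSE, nrow(usnp), length(sets),
              dimnames = list(NULL, names(sets)))
  for (s in names(sets)) {
    ov <- snp_enhancer_overlap(usnp, sets[[s]], radius_bp)
    H[unique(ov$snp), s] <- TRUE
  }
  H
}

#' Flat hypergeometric GWAS enrichment
#'
#' For each (annotation set, study) pair, the upper-tail hypergeometric
#' p-value of the 2x2 table (trait SNPs captured by the set; catalog SNPs
#' captured; trait SNPs; catalog SNPs), over unique SNP positions: a SNP
#' reported by several studies counts once in the catalog background and
#' once per study in the study counts. All pairs of one call form a single
#' BH family.
#'
#' @param pruned pruned catalog (see [prune_catalog()]).
#' @param sets named list of enhancer-interval data.frames (the annotation
#'   sets, e.g. per-biosample active enhancers).
#' @param alpha BH significance level (default 0.05).
#' @param radius_bp midpoint-overlap radius (default 2,500).
#' @return data.table: set, trait, pubmed_id, k, K, n, N, p_hyper, p_bh,
#'   significant.
#' @export
flat_enrichment <- function(pruned, sets, alpha = 0.05, radius_bp = 2500L) {
  ui <- unique_snp_index(pruned)
  N <- nrow(ui$usnp)
  if (N == 0L) stop("empty catalog")
  H <- snp_set_hit_matrix(ui$usnp, sets, radius_bp)
  K <- colSums(H)
  assoc <- ui$assoc
  assoc[, study := paste(trait, pubmed_id, sep = "|")]
  out <- list()
  for (st in unique(assoc$study)) {
    idx <- unique(assoc$usnp_idx[assoc$study == st])
    n <- length(idx)
    k <- colSums(H[idx, , drop = FALSE])
    first <- assoc[assoc$study == st, ][1, ]
    out[[st]] <- data.table::data.table(
      set = names(sets), trait = first$trait, pubmed_id = first$pubmed_id,
      k = as.integer(k), K = as.integer(K), n = n, N = N,
      p_hyper = hyper_tail_p(k, K, n, N))
  }
  res <- data.table::rbindlist(out)
  res[, p_bh := stats::p.adjust(p_hyper, method = "BH")]
  res[, significant := p_bh <= alpha]
  res[]
}

#' Empirical FDR by trait-label shuffling
#'
#' Builds `n_shuffles` null catalogs by globally permuting the study labels
#' across associations (positions fixed, genotype-phenotype links broken),
#' recomputes the enrichment on each, and reports the mean number of
#' significant (set, study) pairs in the shuffles divided by the number in
#' the real catalog. Significance is the caller's rule: BH-adjusted or
#' nominal p-values at `alpha`.
#'
#' @inheritParams flat_enrichment
#' @param n_shuffles number of shuffled catalogs (default 100).
#' @param seed RNG seed for the shuffle sequence.
#' @param adjust `"BH"` (default) or `"none"`.
#' @return list: `fdr` (NA with a warning when the real catalog has no
#'   significant pair), `n_significant_real`, `shuffle_counts`, and the
#'   real enrichment `table`.
#' @export
empirical_fdr <- function(pruned, sets, n_shuffles = 100L, seed = 1L,
                          alpha = 0.05, adjust = c("BH", "none"),
                          radius_bp = 2500L) {
  adjust <- match.arg(adjust)
  pruned <- data.table::as.data.table(pruned)
  if (length(unique(pruned$trait)) < 2L) stop("need at least 2 traits")
  ui <- unique_snp_index(pruned)
  N <- nrow(ui$usnp)
  H <- snp_set_hit_matrix(ui$usnp, sets, radius_bp)
  K <- colSums(H)
  assoc <- ui$assoc
  assoc[, study := paste(trait, pubmed_id, sep = "|")]

  count_significant <- function(labels) {
    ps <- unlist(lapply(split(assoc$usnp_idx, labels), function(idx) {
      idx <- unique(idx)
      hyper_tail_p(colSums(H[idx, , drop = FALSE]), K, length(idx), N)
    }), use.names = FALSE)
    padj <- if (adjust == "BH") stats::p.adjust(ps, "BH") else ps
    sum(padj <= alpha)
  }

  n_real <- count_significant(assoc$study)
  set.seed(derive_seed(seed, "catalog"))
  shuffle_counts <- vapply(seq_len(n_shuffles), function(i)
    count_significant(sample(assoc$study)), 0)
  if (n_real == 0L) {
    warning("no significant combinations in the real catalog; FDR undefined")
    fdr <- NA_real_
  } else {
    fdr <- mean(shuffle_counts) / n_real
  }
  list(fdr = fdr, n_significant_real = n_real,
       shuffle_counts = shuffle_counts,
       table = flat_enrichment(pruned, sets, alpha, radius_bp))
}

#' Build the biosample tree with consensus enhancer sets
#'
#' Complete-linkage agglomerative clustering of biosamples under the
#' Jaccard distance of their binary enhancer sets, with a deterministic
#' tie-break (among equally distant pairs, the one whose smallest original
#' sample index is lowest merges first). Each node carries its consensus
#' set - the enhancers present in every leaf of its subtree, computed
#' bottom-up by intersection - so every node's consensus is a superset of
#' its parent's. The tested set of a node is its consensus minus its
#' parent's consensus (the root's tested set is its full consensus).
#'
#' @param A binary elements x biosamples matrix (or `activity_matrix`).
#' @return a `biosample_tree`: list of per-node records (id, children,
#'   parent, height, leaves, consensus row indices, tested row indices)
#'   plus `labels` and the element ids.
#' @export
build_tree <- function(A) {
  if (inherits(A, "activity_matrix")) {
    elements <- A$elements
    A <- A$A
  } else elements <- NULL
  A <- (A > 0) * 1
  n <- ncol(A)
  if (n < 2L) stop("need at least 2 biosamples")
  labels <- colnames(A) %||% as.character(seq_len(n))
  D <- 1 - jaccard_sim_columns(A)

  nodes <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) {
    nodes[[i]] <- list(id = i, children = integer(0), parent = NA_integer_,
                       height = 0, leaves = i,
                       consensus = which(A[, i] > 0))
  }
  active <- seq_len(n)              # cluster -> node id
  rep_idx <- seq_len(n)             # smallest original sample index
  cd <- D                           # complete-linkage cluster distances
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(NA, NA); best_d <- Inf; best_rep <- c(Inf, Inf)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- cd[i, j]
        rp <- sort(c(rep_idx[i], rep_idx[j]))
        if (dij < best_d - 1e-12 ||
            (abs(dij - best_d) <= 1e-12 &&
             (rp[1] < best_rep[1] ||
              (rp[1] == best_rep[1] && rp[2] < best_rep[2])))) {
          best <- c(i, j); best_d <- dij; best_rep <- rp
        }
      }
    }
    i <- best[1]; j <- best[2]
    new_id <- n + step
    a <- active[i]; b <- active[j]
    nodes[[new_id]] <- list(
      id = new_id, children = c(a, b), parent = NA_integer_,
      height = best_d,
      leaves = sort(c(nodes[[a]]$leaves, nodes[[b]]$leaves)),
      consensus = intersect(nodes[[a]]$consensus, nodes[[b]]$consensus)
    )
    nodes[[a]]$parent <- new_id
    nodes[[b]]$parent <- new_id
    newd <- pmax(cd[i, ], cd[j, ])[-c(i, j)]
    cd <- cd[-c(i, j), -c(i, j), drop = FALSE]
    cd <- rbind(cbind(cd, newd), c(newd, 0))
    active <- c(active[-c(i, j)], new_id)
    rep_idx <- c(rep_idx[-c(i, j)], min(best_rep))
  }
  root <- 2L * n - 1L
  for (v in seq_along(nodes)) {
    p <- nodes[[v]]$parent
    nodes[[v]]$tested <- if (is.na(p)) nodes[[v]]$consensus else
      setdiff(nodes[[v]]$consensus, nodes[[p]]$consensus)
  }
  structure(list(nodes = nodes, labels = labels, n_leaves = n, root = root,
                 elements = elements,
                 element_ids = rownames(A) %||% as.character(seq_len(nrow(A)))),
            class = "biosample_tree")
}

#' @export
print.biosample_tree <- function(x, ...) {
  cat(sprintf("<biosample_tree> %d leaves, %d nodes; root consensus %d\n",
              x$n_leaves, length(x$nodes),
              length(x$nodes[[x$root]]$consensus)))
  invisible(x)
}

#' Convert a biosample tree to hclust / Newick
#'
#' @param tree a `biosample_tree`.
#' @return `as_hclust` returns a `stats::hclust` object; `tree_newick`
#'   returns a Newick string with node labels.
#' @export
as_hclust <- function(tree) {
  n <- tree$n_leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    nd <- tree$nodes[[n + s]]
    merge[s, ] <- vapply(nd$children, function(c)
      if (c <= n) -c else c - n, 0L)
    height[s] <- nd$height
  }
  ord <- integer(0)
  walk <- function(v) {
    if (v <= n) ord <<- c(ord, v)
    else for (c in tree$nodes[[v]]$children) walk(c)
  }
  walk(tree$root)
  structure(list(merge = merge, height = height, order = ord,
                 labels = tree$labels, method = "complete",
                 call = match.call(), dist.method = "jaccard"),
            class = "hclust")
}

#' @rdname as_hclust
#' @export
tree_newick <- function(tree) {
  phy <- ape::as.phylo(as_hclust(tree))
  phy$node.label <- paste0("node", (tree$n_leaves + 1L):(2L * tree$n_leaves - 1L))
  ape::write.tree(phy)
}

#' Tree-based GWAS enrichment over node tested sets
#'
#' For every (node, study) pair, the upper-tail hypergeometric test of
#' trait-SNP hits in the node's tested enhancer set (consensus minus parent
#' consensus by default; `tested = "consensus"` uses the full consensus
#' set). Nodes with an empty tested set are skipped and recorded. BH
#' correction spans all computed (node, study) pairs.
#'
#' @param pruned pruned catalog.
#' @param tree a `biosample_tree` built from an `activity_matrix` (so
#'   element intervals are available), or pass `elements` explicitly.
#' @param elements optional data.frame of element intervals matching the
#'   activity-matrix rows.
#' @param alpha BH level.
#' @param tested `"differential"` (default) or `"consensus"`.
#' @param radius_bp midpoint-overlap radius.
#' @return data.table: node, trait, pubmed_id, k, K, n, N, p_hyper, p_bh,
#'   significant, tested_size, consensus_size; attribute `skipped` lists
#'   empty-tested-set nodes.
#' @export
tree_enrichment <- function(pruned, tree, elements = NULL, alpha = 0.05,
                            tested = c("differential", "consensus"),
                            radius_bp = 2500L) {
  tested <- match.arg(tested)
  elements <- data.table::as.data.table(elements %||% tree$elements)
  if (is.null(elements) || nrow(elements) == 0L)
    stop("element intervals required")
  ui <- unique_snp_index(pruned)
  N <- nrow(ui$usnp)
  ov <- snp_enhancer_overlap(ui$usnp, elements, radius_bp)
  elem_row <- match(ov$enhancer, elements$id)
  hits_by_elem <- split(ov$snp, elem_row)
  assoc <- ui$assoc
  assoc[, study := paste(trait, pubmed_id, sep = "|")]
  studies <- split(assoc, assoc$study)

  node_hit_snps <- function(rows) {
    if (!length(rows)) return(integer(0))
    unique(unlist(hits_by_elem[as.character(rows)], use.names = FALSE))
  }
  out <- list(); skipped <- integer(0)
  for (v in seq_along(tree$nodes)) {
    nd <- tree$nodes[[v]]
    set_rows <- if (tested == "differential") nd$tested else nd$consensus
    if (!length(set_rows)) {
      skipped <- c(skipped, v)
      next
    }
    hit <- node_hit_snps(set_rows)
    K <- length(hit)
    for (st in names(studies)) {
      idx <- unique(studies[[st]]$usnp_idx)
      k <- sum(idx %in% hit)
      out[[length(out) + 1L]] <- data.table::data.table(
        node = v, trait = studies[[st]]$trait[1],
        pubmed_id = studies[[st]]$pubmed_id[1],
        k = k, K = K, n = length(idx), N = N,
        p_hyper = hyper_tail_p(k, K, length(idx), N),
        tested_size = length(nd$tested),
        consensus_size = length(nd$consensus))
    }
  }
  res <- data.table::rbindlist(out)
  res[, p_bh := stats::p.adjust(p_hyper, method = "BH")]
  res[, significant := p_bh <= alpha]
  data.table::setattr(res, "skipped", skipped)
  res[]
}

#' Greedy rarefaction curve over flat enrichments
#'
#' Iteratively adds the annotation set covering the most still-uncovered
#' studies (covered = significantly enriched); when no remaining set is
#' significant for any uncovered study, the (set, study) pair with maximal
#' -log10 p is added instead. Ties break by set id. Stops when every study
#' is covered.
#'
#' @param enrichment a [flat_enrichment()] table.
#' @return data.table: step, set, n_new, cumulative, via
#'   (`"significant"` or `"max_enrichment"`), new_traits (comma-separated
#'   study keys).
#' @export
rarefaction_curve <- function(enrichment) {
  dt <- data.table::as.data.table(enrichment)
  if (nrow(dt) == 0L) stop("empty enrichment table")
  dt[, study := paste(trait, pubmed_id, sep = "|")]
  traits <- unique(dt$study)
  uncovered <- traits
  steps <- list()
  while (length(uncovered)) {
    sig <- dt[dt$significant & dt$study %in% uncovered, ]
    if (nrow(sig)) {
      cnt <- sig[, .N, by = set][order(-N, set)]
      pick <- cnt$set[1]
      newly <- sig$study[sig$set == pick]
      via <- "significant"
    } else {
      rem <- dt[dt$study %in% uncovered, ]
      rem <- rem[order(rem$p_hyper, rem$set), ]
      pick <- rem$set[1]
      newly <- rem$study[1]
      via <- "max_enrichment"
    }
    uncovered <- setdiff(uncovered, newly)
    steps[[length(steps) + 1L]] <- data.table::data.table(
      step = length(steps) + 1L, set = pick, n_new = length(newly),
      cumulative = length(traits) - length(uncovered), via = via,
      new_traits = paste(sort(newly), collapse = ","))
  }
  data.table::rbindlist(steps)
}
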