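# Tissue-level aggregation of tree enrichments: node tissue labels,
# tissue x trait matrices, trait classification, Jaccard tissue similarity
# with fixed-marginal permutation nulls, trait-trait networks (epigenetic
# cosine and genetic 10-kb-bin overlap), nearest-expressed-gene selection
# and gene-set over-representation, and locus co-association.

#' Assign each tree node to a tissue
#'
#' A node is labelled with a tissue iff strictly more than 50% of its
#' leaves belong to that tissue group, and `"multiple"` otherwise; leaves
#' take their own group.
#'
#' @param tree a `biosample_tree`.
#' @param metadata data.frame with `sample` and `group` covering all
#'   leaves.
#' @return named character vector, one label per node id.
#' @export
assign_node_tissues <- function(tree, metadata) {
  metadata <- data.table::as.data.table(metadata)
  grp <- metadata$group[match(tree$labels, metadata$sample)]
  if (any(is.na(grp))) stop("leaf without metadata")
  vapply(seq_along(tree$nodes), function(v) {
    g <- grp[tree$nodes[[v]]$leaves]
    tab <- table(g)
    top <- which.max(tab)
    if (tab[top] > length(g) / 2) names(tab)[top] else "multiple"
  }, "")
}

#' Tissue-by-trait enrichment matrix
#'
#' Entry (tissue, study) is the sum of -log10 p over that tissue's
#' significant (BH-passing) nodes in a tree enrichment table.
#'
#' @param tree_enr a [tree_enrichment()] table.
#' @param node_labels output of [assign_node_tissues()].
#' @param significant_only restrict to BH-significant nodes (default TRUE).
#' @return numeric matrix, tissues (rows, including `"multiple"` when
#'   labelled) x studies.
#' @export
tissue_trait_matrix <- function(tree_enr, node_labels,
                                significant_only = TRUE) {
  dt <- data.table::as.data.table(tree_enr)
  dt[, study := paste(trait, pubmed_id, sep = "|")]
  if (max(dt$node) > length(node_labels)) stop("label/table mismatch")
  tissues <- sort(unique(node_labels))
  studies <- sort(unique(dt$study))
  M <- matrix(0, length(tissues), length(studies),
              dimnames = list(tissues, studies))
  use <- if (significant_only) dt[dt$significant, ] else dt
  if (nrow(use)) {
    use[, tissue := node_labels[node]]
    agg <- use[, list(v = sum(-log10(pmax(p_hyper, 1e-300)))),
               by = list(tissue, study)]
    M[cbind(match(agg$tissue, tissues), match(agg$study, studies))] <- agg$v
  }
  M
}

#' Column-normalize a tissue-by-trait matrix
#'
#' Scales each column to sum to 1 (columns summing to 0 are left at 0),
#' giving the proportion of enrichment significance attributed to each
#' tissue per trait.
#'
#' @param M non-negative matrix.
#' @export
normalize_columns <- function(M) {
  cs <- colSums(M)
  sweep(M, 2, ifelse(cs > 0, cs, 1), "/")
}

#' Classify traits by the number of enriched tissues
#'
#' Unifactorial traits are enriched in exactly one tissue group,
#' multifactorial in two or more, and polyfactorial in at least
#' `poly_threshold` (reported as their own class). Zero-column traits are
#' excluded with a warning.
#'
#' @param B binary tissue x trait matrix (e.g. `tissue_trait_matrix(...) > 0`).
#' @param poly_threshold polyfactorial cutoff (default 10).
#' @return data.table: trait, n_tissues, class.
#' @export
classify_traits <- function(B, poly_threshold = 10L) {
  cnt <- colSums(B > 0)
  if (any(cnt == 0))
    warning("excluding trait(s) with no enriched tissue: ",
            paste(colnames(B)[cnt == 0], collapse = ", "))
  keep <- cnt > 0
  cls <- ifelse(cnt[keep] >= poly_threshold, "polyfactorial",
                ifelse(cnt[keep] >= 2, "multifactorial", "unifactorial"))
  data.table::data.table(trait = colnames(B)[keep],
                         n_tissues = as.integer(cnt[keep]), class = cls)
}

#' Jaccard tissue-similarity matrix
#'
#' `J(a, b)` = traits enriched in both tissues / traits enriched in either;
#' rows with no enriched trait get 0 everywhere (1 on the diagonal only
#' when non-empty).
#'
#' @param B binary tissue x trait matrix.
#' @return symmetric tissue x tissue matrix.
#' @export
tissue_similarity <- function(B) {
  B <- (B > 0) * 1
  inter <- B %*% t(B)
  rs <- rowSums(B)
  union <- outer(rs, rs, "+") - inter
  J <- inter / union
  J[union == 0] <- 0
  J
}

# One checkerboard swap chain step sequence on a binary matrix: picks two
# 1-entries at random; if they span a checkerboard (the opposite corners are
# 0), swaps them. Preserves all row and column sums. Returns the updated
# matrix after `n_swaps` successful swaps (or errors when the matrix admits
# no swap within the attempt budget).
checkerboard_swaps <- function(B, n_swaps, max_attempts = NULL) {
  ones <- which(B == 1, arr.ind = TRUE)
  if (nrow(ones) < 2L) stop("matrix too sparse to swap")
  max_attempts <- max_attempts %||% (200L * n_swaps + 1000L)
  done <- 0L; attempts <- 0L
  while (done < n_swaps) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("no swappable checkerboard found within attempt budget")
    ij <- sample.int(nrow(ones), 2L)
    r1 <- ones[ij[1], 1]; c1 <- ones[ij[1], 2]
    r2 <- ones[ij[2], 1]; c2 <- ones[ij[2], 2]
    if (r1 == r2 || c1 == c2 || B[r1, c2] == 1 || B[r2, c1] == 1) next
    B[r1, c1] <- 0; B[r2, c2] <- 0
    B[r1, c2] <- 1; B[r2, c1] <- 1
    ones[ij[1], ] <- c(r1, c2)
    ones[ij[2], ] <- c(r2, c1)
    done <- done + 1L
  }
  B
}

#' Fixed-marginal permutation null for tissue co-enrichment
#'
#' Holds the rows of the focal tissue's nodes fixed and rewires the rest of
#' the binary node x trait enrichment matrix by degree-preserving
#' checkerboard swaps (10 x the number of ones per permutation sample,
#' after an equal burn-in), collapses each permuted matrix to a binary
#' tissue x trait matrix, and records for every other tissue the overlap
#' (traits enriched in both the focal and the other tissue) plus the cosine
#' distance of the permuted matrix to the original. Row and column sums of
#' the permuted block are asserted unchanged at every sample.
#'
#' @param B binary node x trait matrix.
#' @param node_labels tissue label per row of `B`.
#' @param focal_tissue tissue whose rows stay fixed.
#' @param n_perm number of permutation samples (default 10,000).
#' @param seed RNG seed.
#' @return list: `p` (data.table tissue / observed overlap / empirical p
#'   `(1 + #\{perm >= obs\}) / (1 + n_perm)`), `cosine_distances`, `n_perm`.
#'   When the matrix admits no checkerboard swap the permutation
#'   distribution is a point mass at the observed matrix and every p is 1
#'   (with a warning).
#' @export
permutation_null <- function(B, node_labels, focal_tissue, n_perm = 10000L,
                             seed = 1L) {
  stopifnot(nrow(B) == length(node_labels), all(B %in% c(0, 1)))
  set.seed(derive_seed(seed, "traits"))
  fixed <- node_labels == focal_tissue
  free <- B[!fixed, , drop = FALSE]
  free_labels <- node_labels[!fixed]
  tissues <- setdiff(sort(unique(node_labels)), focal_tissue)
  collapse <- function(mat) {
    vapply(tissues, function(t)
      colSums(mat[free_labels == t, , drop = FALSE]) > 0,
      logical(ncol(B)))
  }
  focal_row <- colSums(B[fixed, , drop = FALSE]) > 0
  obs_overlap <- colSums(collapse(free) & focal_row)
  n_swaps <- 10L * sum(free)
  perm_ge <- stats::setNames(numeric(length(tissues)), tissues)
  cosd <- numeric(n_perm)
  rs0 <- rowSums(free); cs0 <- colSums(free)
  vB <- as.numeric(B)
  cur <- tryCatch(checkerboard_swaps(free, n_swaps),  # burn-in
                  error = function(e) NULL)
  if (is.null(cur)) {
    # no checkerboard exists: the conditional null given the marginals is a
    # point mass at the observed matrix, so every overlap "permutation"
    # equals the observed one
    warning("matrix admits no checkerboard swap; ",
            "permutation distribution is degenerate")
    return(list(p = data.table::data.table(tissue = tissues,
                                           observed = as.numeric(obs_overlap),
                                           p = 1),
                cosine_distances = rep(0, n_perm), n_perm = n_perm))
  }
  for (i in seq_len(n_perm)) {
    cur <- checkerboard_swaps(cur, n_swaps)
    stopifnot(identical(rowSums(cur), rs0), identical(colSums(cur), cs0))
    ov <- colSums(collapse(cur) & focal_row)
    perm_ge <- perm_ge + (ov >= obs_overlap)
    full <- B
    full[!fixed, ] <- cur
    v <- as.numeric(full)
    cosd[i] <- 1 - sum(v * vB) / sqrt(sum(v^2) * sum(vB^2))
  }
  list(
    p = data.table::data.table(tissue = tissues,
                               observed = as.numeric(obs_overlap),
                               p = (1 + perm_ge) / (1 + n_perm)),
    cosine_distances = cosd, n_perm = n_perm
  )
}

#' Cross-trait network from tissue enrichment profiles
#'
#' Edges connect trait pairs whose column-normalized tissue profiles are
#' within `edge_threshold` cosine distance; each edge is labelled with the
#' tissue maximizing the elementwise product of the two profiles, each node
#' with its maximal tissue. A force-directed layout (presentation only) is
#' computed when igraph is available, deterministically under
#' `layout_seed`.
#'
#' @param M tissue x trait matrix (raw sums; columns are normalized
#'   internally).
#' @param edge_threshold cosine-distance cutoff (default 0.25).
#' @param layout_seed seed for the optional layout.
#' @return list: `nodes` (trait, max_tissue, total), `edges` (trait_a,
#'   trait_b, cosine_distance, tissue), `layout` (matrix or NULL).
#' @export
trait_network <- function(M, edge_threshold = 0.25, layout_seed = 1L) {
  if (ncol(M) < 2L) stop("need at least 2 traits")
  P <- normalize_columns(M)
  norms <- sqrt(colSums(P^2))
  live <- norms > 0
  edges <- list()
  traits <- colnames(P)
  for (i in seq_len(ncol(P) - 1L)) {
    for (j in (i + 1L):ncol(P)) {
      if (!live[i] || !live[j]) next
      d <- 1 - sum(P[, i] * P[, j]) / (norms[i] * norms[j])
      if (d <= edge_threshold) {
        prod <- P[, i] * P[, j]
        edges[[length(edges) + 1L]] <- data.table::data.table(
          trait_a = traits[i], trait_b = traits[j], cosine_distance = d,
          tissue = rownames(P)[which.max(prod)])
      }
    }
  }
  edges <- if (length(edges)) data.table::rbindlist(edges) else
    data.table::data.table(trait_a = character(0), trait_b = character(0),
                           cosine_distance = numeric(0), tissue = character(0))
  nodes <- data.table::data.table(
    trait = traits,
    max_tissue = rownames(P)[apply(P, 2, which.max)],
    total = colSums(M))
  layout <- NULL
  if (nrow(edges) && requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                       vertices = nodes$trait)
    set.seed(layout_seed)
    layout <- igraph::layout_with_fr(g)
    rownames(layout) <- nodes$trait
  }
  list(nodes = nodes, edges = edges, layout = layout)
}

#' Genetic-overlap network from shared 10-kb SNP bins
#'
#' SNPs of each study are binned into fixed windows from the start of each
#' chromosome; study pairs sharing at least `min_jaccard` of their occupied
#' bins (Jaccard) form edges.
#'
#' @param pruned pruned catalog.
#' @param bin_bp window size (default 10,000).
#' @param min_jaccard edge threshold (default 0.01; the stricter 0.05 rule
#'   can be requested instead).
#' @return data.table: trait_a, trait_b, jaccard, n_shared, n_union.
#' @export
genetic_overlap_network <- function(pruned, bin_bp = 10000L,
                                    min_jaccard = 0.01) {
  dt <- data.table::as.data.table(pruned)
  dt[, study := paste(trait, pubmed_id, sep = "|")]
  dt[, bin := paste(chrom, (pos - 1L) %/% bin_bp)]
  bins <- lapply(split(dt$bin, dt$study), unique)
  studies <- names(bins)
  out <- list()
  for (i in seq_along(studies)[-length(studies)]) {
    for (j in (i + 1L):length(studies)) {
      shared <- length(intersect(bins[[i]], bins[[j]]))
      uni <- length(union(bins[[i]], bins[[j]]))
      jac <- if (uni == 0) 0 else shared / uni
      if (jac >= min_jaccard)
        out[[length(out) + 1L]] <- data.table::data.table(
          trait_a = studies[i], trait_b = studies[j], jaccard = jac,
          n_shared = shared, n_union = uni)
    }
  }
  if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(trait_a = character(0), trait_b = character(0),
                           jaccard = numeric(0), n_shared = integer(0),
                           n_union = integer(0))
}

#' Nearest expressed gene for lead-SNP enhancers
#'
#' For each enhancer, the gene with the nearest TSS (midpoint distance)
#' among genes whose mean expression over the tissue group's biosamples is
#' at least `floor` log2 FPKM; equidistant genes resolve to the lower
#' coordinate. Filtering precedes the nearest-neighbour search.
#'
#' @param enhancers data.frame of enhancer intervals hit by lead SNPs.
#' @param tss data.frame: gene, chrom, pos.
#' @param expression genes x biosamples matrix (log2 FPKM).
#' @param group_samples biosample ids of the tissue group.
#' @param floor expression floor (default 2.0).
#' @return data.table: enhancer, gene, distance.
#' @export
nearest_expressed_gene <- function(enhancers, tss, expression, group_samples,
                                   floor = 2.0) {
  enh <- data.table::as.data.table(enhancers)
  tss <- data.table::as.data.table(tss)
  keep <- intersect(group_samples, colnames(expression))
  if (!length(keep)) stop("expression lacks the group's biosamples")
  avg <- rowMeans(expression[, keep, drop = FALSE])
  expressed <- tss[tss$gene %in% names(avg)[avg >= floor], ]
  mid <- (enh$start + enh$end) %/% 2L
  out <- vector("list", nrow(enh))
  for (i in seq_len(nrow(enh))) {
    cand <- expressed[expressed$chrom == enh$chrom[i], ]
    if (nrow(cand) == 0L)
      stop("no expressed gene on ", enh$chrom[i])
    d <- abs(cand$pos - mid[i])
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.min(cand$pos[best])]
    out[[i]] <- data.table::data.table(enhancer = enh$id[i],
                                       gene = cand$gene[best],
                                       distance = d[best])
  }
  data.table::rbindlist(out)
}

#' Gene-set over-representation
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and
#' each gene set against an expressed-gene background, BH-corrected across
#' sets.
#'
#' @param genes character gene list (must lie within `background`).
#' @param gene_sets named list of character vectors.
#' @param background character background universe.
#' @param alpha BH level.
#' @return data.table: set, k, K, n, N, p, p_bh, significant.
#' @export
geneset_overrepresentation <- function(genes, gene_sets, background,
                                       alpha = 0.05) {
  if (length(background) == 0L) stop("empty background")
  background <- unique(background)
  genes <- unique(genes)
  if (!all(genes %in% background))
    stop("gene list must be a subset of the background")
  N <- length(background)
  n <- length(genes)
  res <- data.table::rbindlist(lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), background)
    k <- length(intersect(genes, set))
    data.table::data.table(set = s, k = k, K = length(set), n = n, N = N,
                           p = hyper_tail_p(k, length(set), n, N))
  }))
  res[, p_bh := stats::p.adjust(p, method = "BH")]
  res[, significant := p_bh <= alpha]
  res[]
}

#' Locus co-association between two traits within node enhancers
#'
#' For each node enhancer set, the focal trait's loci are split into those
#' co-locating with the other trait's loci (both hit the same node
#' enhancer under the midpoint rule) and the rest, and a one-tailed
#' Mann-Whitney test asks whether co-locating loci are more significant
#' (larger -log10 p). This operationalizes the co-association display; the
#' exact two-sample construction is this package's reading and is isolated
#' here.
#'
#' @param focal_loci,other_loci data.frames: chrom, pos, pvalue.
#' @param node_sets named list of node enhancer-interval data.frames.
#' @param radius_bp midpoint-overlap radius (default 2,500).
#' @return data.table: node, n_overlap, n_rest, p (NA when either group is
#'   empty or has fewer than 1 locus).
#' @export
coassociation <- function(focal_loci, other_loci, node_sets,
                          radius_bp = 2500L) {
  focal <- data.table::as.data.table(focal_loci)
  other <- data.table::as.data.table(other_loci)
  if (nrow(focal) < 2L || nrow(other) < 2L)
    stop("need at least 2 loci per trait")
  out <- lapply(names(node_sets), function(nm) {
    enh <- node_sets[[nm]]
    fo <- snp_enhancer_overlap(focal, enh, radius_bp)
    oo <- snp_enhancer_overlap(other, enh, radius_bp)
    shared_enh <- intersect(fo$enhancer, oo$enhancer)
    in_overlap <- unique(fo$snp[fo$enhancer %in% shared_enh])
    x <- -log10(focal$pvalue[in_overlap])
    y <- -log10(focal$pvalue[-in_overlap])
    if (length(in_overlap) == 0L) y <- -log10(focal$pvalue)
    p <- if (length(x) == 0L || length(y) == 0L) NA_real_ else
      stats::wilcox.test(x, y, alternative = "greater")$p.value
    data.table::data.table(node = nm, n_overlap = length(x),
                           n_rest = length(y), p = p)
  })
  data.table::rbindlist(out)
}
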