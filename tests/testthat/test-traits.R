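make_label_tree <- function() {
  A <- cbind(h1 = c(1, 1, 0), h2 = c(1, 1, 0), l1 = c(1, 0, 1))
  rownames(A) <- paste0("e", 1:3)
  build_tree(A)
}

test_that("node tissue labels require a strict majority of leaves", {
  tree <- make_label_tree()
  meta <- data.frame(sample = c("h1", "h2", "l1"),
                     group = c("heart", "heart", "lung"))
  lab <- assign_node_tissues(tree, meta)
  expect_identical(lab[1:3], c("heart", "heart", "lung"))  # leaves
  expect_identical(unname(lab[tree$root]), "heart")        # 2/3 majority
  # a 50/50 node is "multiple"
  A2 <- cbind(h1 = c(1, 0), l1 = c(0, 1))
  rownames(A2) <- c("e1", "e2")
  lab2 <- assign_node_tissues(build_tree(A2), meta)
  expect_identical(unname(lab2[3]), "multiple")
  expect_error(assign_node_tissues(tree, meta[1:2, ]), "without metadata")
})

test_that("tissue-trait entries add -log10 p over significant nodes", {
  enr <- data.table::data.table(
    node = c(4L, 5L, 5L), trait = "tA", pubmed_id = 1L,
    p_hyper = c(1e-4, 1e-3, 1e-2), significant = c(TRUE, TRUE, TRUE))
  labels <- c("x", "x", "x", "heart", "heart")
  M <- tissue_trait_matrix(enr[1, ], labels)
  expect_equal(M["heart", "tA|1"], 4)
  # two heart nodes at 1e-3 and 1e-2 sum to 5
  M2 <- tissue_trait_matrix(enr[2:3, ], labels)
  expect_equal(M2["heart", "tA|1"], 5)
  # non-significant nodes contribute a zero column
  enr$significant <- FALSE
  M3 <- tissue_trait_matrix(enr, labels)
  expect_true(all(M3 == 0))
  bad <- data.table::data.table(node = 99L, trait = "t", pubmed_id = 1L,
                                p_hyper = 0.5, significant = TRUE)
  expect_error(tissue_trait_matrix(bad, labels[1:3]), "mismatch")
})

test_that("trait classes follow the tissue-count thresholds", {
  B <- matrix(0, 12, 4, dimnames = list(paste0("tis", 1:12),
                                        paste0("t", 1:4)))
  B[1, 1] <- 1           # unifactorial
  B[1:7, 2] <- 1         # multifactorial (7 < 10)
  B[1:12, 3] <- 1        # polyfactorial
  expect_warning(cls <- classify_traits(B), "no enriched tissue")
  expect_identical(cls$class,
                   c("unifactorial", "multifactorial", "polyfactorial"))
  expect_false("t4" %in% cls$trait)
})

test_that("tissue similarity is Jaccard with sane degenerate rows", {
  B <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1), c = c(1, 1, 1, 0),
             d = c(0, 0, 0, 0))
  J <- tissue_similarity(B)
  expect_equal(J["a", "b"], 0.5)   # {t1,t2,t3} vs {t2,t3,t4}
  expect_equal(J["a", "c"], 1)
  expect_equal(J["a", "d"], 0)
  expect_equal(J["d", "d"], 0)
  expect_true(isSymmetric(J))
})

test_that("checkerboard swaps preserve marginals and mix the matrix", {
  set.seed(12)
  B <- matrix(rbinom(96, 1, 0.35), 12, 8)
  out <- enhancermap:::checkerboard_swaps(B, 500)
  expect_identical(rowSums(out), rowSums(B))
  expect_identical(colSums(out), colSums(B))
  expect_false(identical(out, B))
  expect_error(enhancermap:::checkerboard_swaps(diag(1, 3) * 0, 10),
               "too sparse")
})

test_that("permutation null detects planted co-enrichment and is calibrated", {
  labels <- rep(c("heart", "lung", "brain"), each = 10)
  # heart (fixed) and lung co-enriched in traits 1-10; brain in 11-20.
  # The free block is a 20x20 permutation matrix, so the fixed-marginal
  # null scatters lung ones uniformly and the observed overlap of 10 is
  # extreme (hypergeometric point mass 1/C(20,10)).
  B <- matrix(0, 30, 20)
  B[cbind(1:10, 1:10)] <- 1
  B[cbind(11:20, 1:10)] <- 1
  B[cbind(21:30, 11:20)] <- 1
  res <- permutation_null(B, labels, "heart", n_perm = 1000, seed = 2)
  expect_lte(res$p$p[res$p$tissue == "lung"], 0.01)
  expect_gt(res$p$p[res$p$tissue == "brain"], 0.5)
  expect_true(all(res$p$p > 0 & res$p$p <= 1))
  expect_equal(length(res$cosine_distances), 1000)
})

test_that("a marginal-determined matrix yields p = 1 with a warning", {
  B <- matrix(1, 4, 5)
  expect_warning(res <- permutation_null(B, rep(c("a", "b"), each = 2), "a",
                                         n_perm = 10, seed = 1),
                 "no checkerboard|degenerate")
  expect_true(all(res$p$p == 1))
})

test_that("trait network edges obey the cosine threshold", {
  M <- cbind(t1 = c(1, 0, 0), t2 = c(1, 0, 0), t3 = c(0, 1, 0),
             t4 = c(1, 1, 0) / sqrt(2))
  rownames(M) <- c("heart", "lung", "brain")
  net <- trait_network(M)
  key <- paste(net$edges$trait_a, net$edges$trait_b)
  expect_true("t1 t2" %in% key)          # identical: distance 0
  expect_false("t1 t3" %in% key)         # orthogonal: distance 1
  expect_false("t1 t4" %in% key)         # 1 - 1/sqrt(2) = 0.293 > 0.25
  expect_equal(net$edges$tissue[key == "t1 t2"], "heart")
  expect_true(all(net$edges$cosine_distance <= 0.25))
  # edge set is monotone in the threshold
  net2 <- trait_network(M, edge_threshold = 0.5)
  expect_true(all(key %in% paste(net2$edges$trait_a, net2$edges$trait_b)))
  expect_error(trait_network(M[, 1, drop = FALSE]), "2 traits")
})

test_that("genetic overlap uses 10-kb bins with exact boundaries", {
  cat <- rbind(
    make_catalog("chr1", c(9999L, 50001L), trait = "tA"),
    make_catalog("chr1", c(10001L, 50001L), trait = "tB", pubmed_id = 2L),
    make_catalog("chr1", c(9998L, 50002L), trait = "tC", pubmed_id = 3L))
  net <- genetic_overlap_network(cat)
  key <- function(a, b) net$jaccard[net$trait_a == a & net$trait_b == b]
  # 9,999 and 10,001 land in different bins: tA and tB share only 50k bin
  expect_equal(key("tA|1", "tB|2"), 1 / 3)
  # identical bin sets give Jaccard 1
  expect_equal(key("tA|1", "tC|3"), 1)
  # threshold filters edges
  expect_equal(nrow(genetic_overlap_network(cat, min_jaccard = 0.5)), 1)
})

test_that("nearest expressed gene filters by the group-mean floor first", {
  enh <- data.frame(chrom = "chr1", start = 100000L, end = 100200L,
                    id = "e1")
  tss <- data.frame(gene = c("near", "far", "other"),
                    chrom = c("chr1", "chr1", "chr2"),
                    pos = c(101000L, 150000L, 1000L))
  expr <- rbind(near = c(5, 5), far = c(4, 4), other = c(5, 5))
  colnames(expr) <- c("s1", "s2")
  res <- nearest_expressed_gene(enh, tss, expr, c("s1", "s2"))
  expect_equal(res$gene, "near")
  # drop the nearest below the floor: second-nearest wins
  expr2 <- expr; expr2["near", ] <- 1
  expect_equal(nearest_expressed_gene(enh, tss, expr2, c("s1", "s2"))$gene,
               "far")
  # equidistant genes resolve to the lower coordinate
  tss3 <- data.frame(gene = c("lo", "hi"), chrom = "chr1",
                     pos = c(100100L - 500L, 100100L + 500L))
  expr3 <- rbind(lo = c(5, 5), hi = c(5, 5))
  colnames(expr3) <- c("s1", "s2")
  expect_equal(nearest_expressed_gene(enh, tss3, expr3, c("s1", "s2"))$gene,
               "lo")
  expect_error(nearest_expressed_gene(enh, tss, expr2 * 0, c("s1", "s2")),
               "no expressed gene")
})

test_that("gene-set over-representation is exact hypergeometric with BH", {
  bg <- paste0("g", 1:50)
  sets <- list(hit = paste0("g", 1:5), none = paste0("g", 40:45))
  res <- geneset_overrepresentation(paste0("g", 1:5), sets, bg)
  expect_equal(res$p[res$set == "hit"], 1 / choose(50, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "none"], 1)
  all_in <- geneset_overrepresentation(bg, list(s = bg), bg)
  expect_equal(all_in$p, 1)
  expect_error(geneset_overrepresentation("gX", sets, bg), "subset")
  expect_error(geneset_overrepresentation("g1", sets, character(0)),
               "empty background")
})

test_that("co-association ranks in-overlap loci by a one-tailed rank test", {
  node <- list(n1 = data.frame(chrom = "chr1",
                               start = c(10000L, 50000L),
                               end = c(10200L, 50200L), id = c("e1", "e2")))
  # focal loci: two in e1 (strong), two far away (weak); other trait in e1
  focal <- data.frame(chrom = "chr1",
                      pos = c(10101L, 10050L, 900000L, 950000L),
                      pvalue = c(1e-20, 1e-18, 1e-8, 1e-8))
  other <- data.frame(chrom = "chr1", pos = c(10120L, 800000L),
                      pvalue = c(1e-10, 1e-9))
  focal$pvalue <- c(1e-20, 1e-18, 1e-8, 1e-7)  # distinct: exact rank test
  res <- coassociation(focal, other, node)
  expect_equal(res$n_overlap, 2)
  # all in-overlap loci more significant than all others: minimal exact p
  expect_equal(res$p, 1 / choose(4, 2), tolerance = 1e-12)
  # empty overlap gives NA
  far <- data.frame(chrom = "chr1", pos = c(700000L, 800000L),
                    pvalue = c(1e-10, 1e-9))
  expect_true(is.na(coassociation(focal, far, node)$p))
  expect_error(coassociation(focal[1, ], other, node), "at least 2")
})
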