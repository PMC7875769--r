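test_that("greedy pruning keeps SNPs by p-value rank at >5 kb spacing", {
  cat <- make_catalog("chr1", c(100000L, 103000L, 110000L),
                      pvalue = c(1e-20, 1e-12, 1e-9))
  pruned <- prune_catalog(cat, min_snps = 1L)
  expect_setequal(pruned$pos, c(100000L, 110000L))

  # HLA removal happens regardless of significance
  hla <- make_catalog("chr6", c(30000000L, 50000000L), pvalue = c(1e-30, 1e-9))
  expect_identical(prune_catalog(hla, min_snps = 1L)$pos, 50000000L)

  # a study left with 9 SNPs after pruning is dropped entirely
  nine <- make_catalog("chr1", seq(1e6, by = 1e5, length.out = 9L))
  expect_equal(nrow(prune_catalog(nine)), 0)
  ten <- make_catalog("chr1", seq(1e6, by = 1e5, length.out = 10L))
  expect_equal(nrow(prune_catalog(ten)), 10)
  # underpowered studies are dropped
  small <- make_catalog("chr1", seq(1e6, by = 1e5, length.out = 10L),
                        sample_size = 9000L)
  expect_equal(nrow(prune_catalog(small)), 0)
  expect_error(prune_catalog(make_catalog("chr1", c(-5L, 10L))), "malformed")
})

test_that("midpoint overlap is inclusive at exactly 2.5 kb", {
  enh <- data.frame(chrom = "chrS1", start = 1000L, end = 1200L, id = "e1")
  # midpoint 1100 (0-based) -> 1101 (1-based); 3601 - 1101 = 2500
  hit <- snp_enhancer_overlap(data.frame(chrom = "chrS1", pos = 3601L), enh)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 2500)
  miss <- snp_enhancer_overlap(data.frame(chrom = "chrS1", pos = 3602L), enh)
  expect_equal(nrow(miss), 0)
  other <- snp_enhancer_overlap(data.frame(chrom = "chrS2", pos = 3601L), enh)
  expect_equal(nrow(other), 0)
})

test_that("flat enrichment p-values equal the enumeration oracle", {
  # construct a catalog realizing N = 20, K = 5, n = 10, k = 4
  pos_all <- seq(1e6, by = 1e6, length.out = 20L)
  cat <- rbind(
    make_catalog("chrS1", pos_all[1:10], trait = "tA", pubmed_id = 1L),
    make_catalog("chrS1", pos_all[11:20], trait = "tB", pubmed_id = 2L))
  in_set <- pos_all[c(1:4, 11)]  # 4 of trait A, 1 of trait B
  set <- data.frame(chrom = "chrS1", start = in_set - 101L,
                    end = in_set + 99L, id = paste0("e", 1:5))
  res <- flat_enrichment(cat, list(s1 = set))
  pA <- res$p_hyper[res$trait == "tA"]
  expect_equal(pA, oracle_hyper_tail(4, 5, 10, 20), tolerance = 1e-12)
  expect_equal(pA,
               (choose(5, 4) * choose(15, 6) + choose(5, 5) * choose(15, 5)) /
                 choose(20, 10), tolerance = 1e-12)
  # everything-in-set and zero-hit cases are exactly 1
  whole <- data.frame(chrom = "chrS1", start = pos_all - 101L,
                      end = pos_all + 99L, id = paste0("w", 1:20))
  res2 <- flat_enrichment(cat, list(all = whole))
  expect_true(all(res2$p_hyper == 1))
  empty <- data.frame(chrom = "chrS2", start = 1L, end = 200L, id = "z")
  res3 <- flat_enrichment(cat, list(none = empty))
  expect_true(all(res3$p_hyper == 1))
  expect_true(all(res3$k == 0))
})

test_that("BH significance is a prefix of the p-sorted family", {
  sc <- small_compendium()
  gc <- generate_gwas_catalog(sc$cfg, sc$comp)
  pruned <- prune_catalog(gc$catalog)
  flat <- fixture("flat_default", function()
    flat_enrichment(pruned, per_sample_sets(sc$act)))
  ord <- order(flat$p_hyper)
  sig <- flat$significant[ord]
  if (any(sig)) expect_true(all(sig[seq_len(max(which(sig)))]))
  # shrinking alpha never enlarges the significant set
  flat01 <- flat_enrichment(pruned, per_sample_sets(sc$act), alpha = 0.01)
  expect_true(all(flat01$significant <= flat$significant))
})

test_that("empirical FDR is seeded, and undefined without real signal", {
  pos_all <- seq(1e6, by = 1e6, length.out = 20L)
  cat <- rbind(
    make_catalog("chrS1", pos_all[1:10], trait = "tA", pubmed_id = 1L),
    make_catalog("chrS1", pos_all[11:20], trait = "tB", pubmed_id = 2L))
  whole <- data.frame(chrom = "chrS1", start = pos_all - 101L,
                      end = pos_all + 99L, id = paste0("w", 1:20))
  expect_warning(
    f <- empirical_fdr(cat, list(all = whole), n_shuffles = 5, seed = 1),
    "FDR undefined")
  expect_true(is.na(f$fdr))
  sc <- small_compendium()
  gc <- generate_gwas_catalog(sc$cfg, sc$comp)
  pruned <- prune_catalog(gc$catalog)
  sets <- per_sample_sets(sc$act)[1:8]
  f1 <- empirical_fdr(pruned, sets, n_shuffles = 10, seed = 7)
  f2 <- empirical_fdr(pruned, sets, n_shuffles = 10, seed = 7)
  expect_identical(f1$shuffle_counts, f2$shuffle_counts)
})

test_that("tree merges identical samples first and intersects consensus", {
  A <- cbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0), s3 = c(0, 1, 1, 1))
  rownames(A) <- paste0("e", 1:4)
  tree <- build_tree(A)
  first <- tree$nodes[[4]]  # first merge
  expect_setequal(tree$labels[first$leaves], c("s1", "s2"))
  expect_equal(first$height, 0)
  root <- tree$nodes[[tree$root]]
  expect_identical(root$consensus,
                   Reduce(intersect, list(which(A[, 1] > 0),
                                          which(A[, 2] > 0),
                                          which(A[, 3] > 0))))
  # superset chain and root tested set
  for (v in seq_along(tree$nodes)) {
    p <- tree$nodes[[v]]$parent
    if (!is.na(p))
      expect_true(all(tree$nodes[[p]]$consensus %in%
                        tree$nodes[[v]]$consensus))
  }
  expect_identical(root$tested, root$consensus)
})

test_that("tree agrees with hclust complete linkage on a tie-free instance", {
  set.seed(41)  # chosen so the pairwise Jaccard distances are tie-free
  A <- matrix(rbinom(30 * 7, 1, 0.4), 30, 7,
              dimnames = list(NULL, paste0("s", 1:7)))
  tree <- build_tree(A)
  D <- as.dist(1 - enhancermap:::jaccard_sim_columns(A))
  skip_if(anyDuplicated(round(as.vector(D), 12)) > 0,
          "distance ties present")
  hc <- hclust(D, method = "complete")
  ours <- as_hclust(tree)
  expect_equal(sort(ours$height), sort(hc$height), tolerance = 1e-12)
  # same partition at every merge height
  for (k in 2:6)
    expect_equal(mclust::adjustedRandIndex(cutree(hc, k),
                                           stats::cutree(ours, k)), 1)
})

test_that("tree enrichment skips empty tested sets and defines leaf sets", {
  A <- cbind(s1 = c(1, 1, 0), s2 = c(1, 1, 0), s3 = c(1, 0, 1))
  rownames(A) <- paste0("e", 1:3)
  elements <- data.frame(chrom = "chrS1",
                         start = c(1000L, 200000L, 400000L),
                         end = c(1200L, 200200L, 400200L),
                         id = paste0("e", 1:3))
  cat <- rbind(make_catalog("chrS1", c(1101L, 200101L), trait = "tA"),
               make_catalog("chrS1", c(400101L, 300000L), trait = "tB",
                            pubmed_id = 2L))
  tree <- build_tree(A)
  te <- tree_enrichment(cat, tree, elements = elements)
  # leaf tested set = leaf consensus minus parent consensus
  n4 <- tree$nodes[[4]]  # s1+s2 merge, consensus e1,e2; parent root (e1)
  expect_setequal(n4$tested, setdiff(n4$consensus,
                                     tree$nodes[[n4$parent]]$consensus))
  # nodes whose consensus equals the parent's are skipped
  skipped <- attr(te, "skipped")
  for (v in skipped)
    expect_equal(length(tree$nodes[[v]]$tested), 0)
  expect_false(any(te$node %in% skipped))
  # ancestor-descendant tested sets are disjoint
  for (v in seq_along(tree$nodes)) {
    p <- tree$nodes[[v]]$parent
    while (!is.na(p)) {
      expect_equal(length(intersect(tree$nodes[[v]]$tested,
                                    tree$nodes[[p]]$tested)), 0)
      p <- tree$nodes[[p]]$parent
    }
  }
})

test_that("newick export labels all leaves and parses with ape", {
  sc <- small_compendium()
  tree <- fixture("tree_default", function() build_tree(sc$act))
  nwk <- tree_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, sc$comp$metadata$sample)
})

test_that("rarefaction greedily covers studies and matches brute force", {
  enr <- data.table::data.table(
    set = rep(c("s1", "s2"), each = 3),
    trait = rep(c("t1", "t2", "t3"), 2), pubmed_id = 1L,
    p_hyper = c(1e-9, 1e-9, 0.5, 0.9, 0.9, 1e-9),
    significant = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  rc <- rarefaction_curve(enr)
  expect_identical(rc$set, c("s1", "s2"))
  expect_identical(rc$n_new, c(2L, 1L))
  # single set significant for everything: one step
  enr2 <- data.table::copy(enr)
  enr2$significant[enr2$set == "s1"] <- TRUE
  expect_equal(nrow(rarefaction_curve(enr2[enr2$set == "s1", ])), 1)
  # when nothing is significant the maximal enrichment is used
  enr3 <- data.table::copy(enr)
  enr3$significant <- FALSE
  rc3 <- rarefaction_curve(enr3)
  expect_true(all(rc3$via == "max_enrichment"))
  expect_equal(rc3$set[1], enr3$set[which.min(enr3$p_hyper)])

  # greedy first step matches exhaustive best-first on random tables
  set.seed(44)
  for (i in 1:20) {
    tab <- data.table::data.table(
      set = rep(paste0("s", 1:6), each = 8),
      trait = rep(paste0("t", 1:8), 6), pubmed_id = 1L,
      p_hyper = runif(48), significant = runif(48) < 0.3)
    if (!any(tab$significant)) next
    rc <- rarefaction_curve(tab)
    best <- max(table(tab$set[tab$significant]))
    expect_equal(rc$n_new[1], best)
  }
})
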