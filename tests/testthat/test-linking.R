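# A tiny deterministic linking universe: 2 chromosomes, expression copied
# from enhancer signal for the true pairs.
make_link_universe <- function(n_samples = 20) {
  set.seed(77)
  elements <- data.table::data.table(
    chrom = c("chrS1", "chrS1", "chrS2"),
    start = c(10000L, 500000L, 10000L),
    end = c(10200L, 500200L, 10200L),
    id = c("e1", "e2", "e3"))
  tss <- data.table::data.table(
    gene = c("g1", "g2", "g3"),
    chrom = c("chrS1", "chrS1", "chrS2"),
    pos = c(20000L, 1010101L, 30000L))
  S <- matrix(rgamma(3 * n_samples, 2, 1), 3,
              dimnames = list(elements$id, paste0("s", seq_len(n_samples))))
  expr <- rbind(g1 = S["e1", ], g2 = rnorm(n_samples, 5),
                g3 = S["e3", ] + rnorm(n_samples, 0, 0.1))
  list(elements = elements, tss = tss, S = S, expr = expr)
}

test_that("candidate features include exact correlations and window gating", {
  u <- make_link_universe()
  cand <- candidate_correlations(u$expr, list(H3K27ac = u$S), u$tss,
                                 u$elements)
  # g1 expression is e1's signal verbatim
  expect_equal(cand$r_H3K27ac[cand$enhancer == "e1" & cand$gene == "g1"], 1)
  # g2 TSS sits 1,000,001 bp from e1's midpoint: outside the strict window
  expect_false(any(cand$enhancer == "e1" & cand$gene == "g2"))
  # but only 510,001 bp from e2's midpoint: inside
  expect_true(any(cand$enhancer == "e2" & cand$gene == "g2"))
  expect_error(candidate_correlations(u$expr[, 1:2], list(H3K27ac = u$S),
                                      u$tss, u$elements), "3 shared")
})

test_that("constant vectors are recorded as r = 0 with a flag", {
  u <- make_link_universe()
  expr <- u$expr
  expr["g1", ] <- 3  # constant expression
  cand <- candidate_correlations(expr, list(H3K27ac = u$S), u$tss,
                                 u$elements)
  row <- cand[cand$enhancer == "e1" & cand$gene == "g1", ]
  expect_equal(row$r_H3K27ac, 0)
  expect_true(row$constant_flag)
})

test_that("negatives pair each positive with a cross-chromosome gene", {
  u <- make_link_universe()
  cand <- candidate_correlations(u$expr, list(H3K27ac = u$S), u$tss,
                                 u$elements)
  neg1 <- make_negatives(cand, u$expr, list(H3K27ac = u$S), u$tss, seed = 4)
  neg2 <- make_negatives(cand, u$expr, list(H3K27ac = u$S), u$tss, seed = 4)
  expect_identical(neg1, neg2)
  gene_chrom <- u$tss$chrom[match(neg1$gene, u$tss$gene)]
  expect_true(all(gene_chrom != neg1$chrom))
  # paired distances are reused so distance cannot separate the classes
  expect_identical(neg1$distance_bp, cand$distance_bp)
  one_chrom <- u$tss[u$tss$chrom == "chrS1", ]
  expect_error(make_negatives(cand, u$expr, list(H3K27ac = u$S), one_chrom,
                              seed = 1),
               "different chromosome|2 chromosomes")
})

test_that("negative correlations center at zero at compendium sample size", {
  set.seed(10)
  n <- 304
  S <- matrix(rgamma(200 * n, 2, 1), 200,
              dimnames = list(paste0("e", 1:200), paste0("s", 1:n)))
  expr <- matrix(rnorm(200 * n), 200,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:n)))
  r <- sapply(1:200, function(i) cor(expr[i, ], S[i, ]))
  expect_lt(mean(abs(r)), 0.06)
  # null distribution of Pearson r at n = 304: |r| < 0.2 for ~99% of pairs
  expect_gte(mean(abs(r) < 0.2), 0.99)
})

test_that("the classifier separates separable features and is seeded", {
  set.seed(20)
  n <- 200
  pos <- data.table::data.table(enhancer = "e", gene = "g", chrom = "c",
                                distance_bp = rnorm(n, 1e4, 1e3),
                                r_H3K27ac = runif(n, 0.7, 1))
  neg <- data.table::copy(pos)
  neg$r_H3K27ac <- runif(n, -0.2, 0.2)
  clf1 <- train_link_classifier(pos, neg, seed = 2)
  clf2 <- train_link_classifier(pos, neg, seed = 2)
  p_pos <- link_probability(clf1, pos)
  p_neg <- link_probability(clf1, neg)
  expect_identical(link_probability(clf2, pos), p_pos)
  expect_equal(mean(c(p_pos > 0.5, p_neg <= 0.5)), 1)  # training accuracy 1
  expect_error(train_link_classifier(pos, pos[0, ], seed = 1), "single-class")

  # features independent of labels carry no signal: held-out AUROC ~ 0.5
  set.seed(21)
  null_feats <- function(m) data.table::data.table(
    enhancer = "e", gene = "g", chrom = "c",
    distance_bp = rnorm(m, 1e4, 1e3), r_H3K27ac = runif(m, -1, 1))
  clf_null <- train_link_classifier(null_feats(300), null_feats(300),
                                    seed = 3)
  hold <- null_feats(600)
  lab <- rep(c(TRUE, FALSE), 300)
  auc <- rank_auc(link_probability(clf_null, hold), lab)
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("kept links require strict threshold exceedance and activity", {
  u <- make_link_universe()
  cand <- candidate_correlations(u$expr, list(H3K27ac = u$S), u$tss,
                                 u$elements)
  pos <- cand[(cand$enhancer == "e1" & cand$gene == "g1") |
                (cand$enhancer == "e3" & cand$gene == "g3"), ]
  neg <- make_negatives(pos, u$expr, list(H3K27ac = u$S), u$tss, seed = 1)
  clf <- train_link_classifier(pos, neg, seed = 1)
  A <- matrix(0L, 3, 2, dimnames = list(c("e1", "e2", "e3"), c("s1", "s2")))
  A["e1", "s1"] <- 1L
  pred <- predict_links(clf, cand, A)
  # only the active (enhancer, biosample) pair emits rows
  expect_true(all(pred$enhancer == "e1" & pred$biosample == "s1"))
  # probability exactly equal to the threshold is not kept
  p <- pred$probability[1]
  pred_at <- predict_links(clf, cand, A, threshold = p)
  expect_false(any(pred_at$kept[pred_at$probability == p]))
  # monotone filtering: higher threshold never enlarges the kept set
  k_lo <- sum(predict_links(clf, cand, A, threshold = 0.3)$kept)
  k_hi <- sum(predict_links(clf, cand, A, threshold = 0.9)$kept)
  expect_lte(k_hi, k_lo)
})

test_that("link evaluation reproduces confusion arithmetic and conventions", {
  gold_pos <- data.frame(enhancer = c("e1", "e2", "e3", "e4"),
                         gene = c("g1", "g2", "g3", "g4"))
  gold_neg <- data.frame(enhancer = c("e5", "e6"), gene = c("g5", "g6"))
  perfect <- evaluate_links(gold_pos, gold_pos, gold_neg)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # 3 TP, 1 FP, 1 FN
  calls <- data.frame(enhancer = c("e1", "e2", "e3", "e5"),
                      gene = c("g1", "g2", "g3", "g5"))
  m <- evaluate_links(calls, gold_pos, gold_neg)
  expect_equal(unlist(m[, c("precision", "recall", "f1")]),
               c(precision = 0.75, recall = 0.75, f1 = 0.75))

  empty <- evaluate_links(gold_pos[0, ], gold_pos, gold_neg)
  expect_equal(empty$precision, 0)
  expect_true(empty$undefined_precision)
  expect_equal(empty$recall, 0)
  expect_error(evaluate_links(calls, gold_pos[0, ], gold_neg), "empty gold")

  # score-only baseline keeps one best gene per enhancer
  scored <- data.frame(enhancer = c("e1", "e1", "e2"),
                       gene = c("g1", "g9", "g2"),
                       score = c(5, 1, 2))
  b <- evaluate_links(scored, gold_pos, gold_neg,
                      mode = "best_per_enhancer")
  expect_equal(b$tp, 2)
  expect_equal(b$fp, 0)
})
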