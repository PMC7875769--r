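test_that("binarization cutoff matches observed exceedance quantiles", {
  x <- c(1, 2, 3)
  expect_equal(binarization_cutoff(x, x), 2)
  expect_equal(binarization_cutoff(x, x / 2), 1)
  set.seed(1)
  obs <- runif(1000, 0, 4)          # ~50% above 2
  imp <- rgamma(1000, 2, 1)
  cut <- binarization_cutoff(obs, imp)
  expect_equal(mean(imp > cut), mean(obs > 2), tolerance = 2e-3)
  # monotone in the observed cutoff
  expect_lte(binarization_cutoff(obs, imp, 1), cut)
  expect_error(binarization_cutoff(numeric(0), imp), "empty")
})

test_that("active-enhancer calls gate on state and flank-weighted signal", {
  dhs <- data.frame(chrom = "chrS1", start = 1000L, end = 1200L, id = "d1")
  seg_enh <- list(chrS1 = c(rep("E18", 5), "E7", rep("E18", 4)))
  seg_prom <- list(chrS1 = c(rep("E18", 5), "E1", rep("E18", 4)))
  # signal 5.0 inside the DHS bin, 0 in the flanks:
  # mean over [900, 1300) = (0.5*0 + 5 + 0.5*0)/2 = 2.5 > 2
  sig <- rep(0, 10); sig[6] <- 5
  tr <- list(s1 = make_track(sig))
  act <- call_active_enhancers(dhs, list(s1 = seg_enh), tr,
                               drop_inactive = FALSE)
  expect_equal(act$A["d1", "s1"], 1L)
  expect_equal(act$S["d1", "s1"], 2.5)
  # promoter state with huge signal is not an active enhancer
  hi <- rep(10, 10)
  act_p <- call_active_enhancers(dhs, list(s1 = seg_prom),
                                 list(s1 = make_track(hi)),
                                 drop_inactive = FALSE)
  expect_equal(act_p$A["d1", "s1"], 0L)
  # but it is an active promoter under the promoter-state gate
  act_p2 <- call_active_enhancers(dhs, list(s1 = seg_prom),
                                  list(s1 = make_track(hi)),
                                  states = PROMOTER_STATES,
                                  drop_inactive = FALSE)
  expect_equal(act_p2$A["d1", "s1"], 1L)
  expect_error(call_active_enhancers(dhs, list(s1 = seg_enh), tr,
                                     states = "E99"), "unknown state")
  bad_dhs <- data.frame(chrom = "chrX", start = 0L, end = 200L, id = "d")
  expect_error(call_active_enhancers(bad_dhs, list(s1 = seg_enh), tr),
               "outside declared")
})

test_that("raising the signal threshold never adds active entries", {
  sc <- small_compendium()
  lo <- sc$act
  hi <- call_active_enhancers(sc$comp$dhs, sc$comp$segmentations,
                              sc$comp$tracks, signal_threshold = 3,
                              drop_inactive = FALSE)
  lo_full <- call_active_enhancers(sc$comp$dhs, sc$comp$segmentations,
                                   sc$comp$tracks, drop_inactive = FALSE)
  expect_true(all(hi$A <= lo_full$A))
})

test_that("element classification applies the strict 75% rule", {
  res <- classify_elements(c(a = 7, b = 6, c = 1, d = 3),
                           c(a = 1, b = 2, c = 7, d = 1))
  expect_identical(res$class, c("enhancer", "dyadic", "promoter", "dyadic"))
  expect_error(classify_elements(0, 0), "zero active")
  # classes partition the elements
  set.seed(5)
  e <- rpois(200, 3); p <- rpois(200, 3)
  keep <- e + p > 0
  cl <- classify_elements(e[keep], p[keep])
  expect_equal(sum(table(cl$class)), sum(keep))
})

test_that("k-centroids recovers distinct rows exactly when k equals them", {
  X <- rbind(matrix(rep(c(1, 1, 0, 0), 5), 5, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 1), 4), 4, 4, byrow = TRUE),
             matrix(rep(c(1, 0, 1, 0), 3), 3, 4, byrow = TRUE))
  rownames(X) <- paste0("e", 1:12)
  ms <- cluster_modules(X, k = 3, seed = 1)
  expect_equal(utils::tail(ms$objective, 1), 0)
  expect_equal(length(unique(ms$assignment)), 3)
  expect_error(cluster_modules(X, k = 4, seed = 1), "distinct rows")
})

test_that("clustering objective is non-increasing and seeded runs identical", {
  sc <- small_compendium()
  A <- sc$act$A
  ms1 <- cluster_modules(A, k = 6, seed = 9)
  ms2 <- cluster_modules(A, k = 6, seed = 9)
  expect_identical(ms1$assignment, ms2$assignment)
  expect_true(all(diff(ms1$objective) <= 1e-12))
})

test_that("noiseless planted modules are recovered with ARI 1", {
  # one module per tissue group so the 6 planted activity patterns are
  # distinct even without noise
  cfg <- synth_config(seed = 8, module_activity_prob = 1, leak_prob = 0,
                      n_tissue_groups = 6, samples_per_group = 2,
                      n_modules = 6, enhancers_per_module = 40, n_genes = 10,
                      broad_module_fraction = 0, chrom_length_bp = 600000L)
  comp <- generate_compendium(cfg)
  act <- call_active_enhancers(comp$dhs, comp$segmentations, comp$tracks)
  ms <- cluster_modules(act$A, k = 6, seed = 1)
  expect_equal(
    mclust::adjustedRandIndex(ms$assignment,
                              comp$truth$module_assignment[names(ms$assignment)]),
    1)
})

test_that("diagonalization puts broad columns first, then argmax order", {
  M <- diag(0.8, 3)
  colnames(M) <- c("c1", "c2", "c3")
  expect_identical(diagonalize(M), c("c1", "c2", "c3"))
  M2 <- cbind(M, broad = c(0.9, 0.9, 0.9))
  expect_identical(diagonalize(M2), c("broad", "c1", "c2", "c3"))
  # two columns with the same argmax row: lexicographic tie-break
  M3 <- cbind(bb = c(0.9, 0.1), aa = c(0.8, 0.2))
  expect_identical(diagonalize(M3), c("aa", "bb"))
})

test_that("metadata enrichment is exact hypergeometric on module inclusion", {
  centers <- matrix(0, 2, 40,
                    dimnames = list(c("m1", "m2"), sprintf("s%02d", 1:40)))
  centers["m1", 1:5] <- 0.9    # exactly the 5 heart samples
  centers["m2", ] <- 0.9       # includes every sample
  meta <- data.frame(sample = sprintf("s%02d", 1:40),
                     group = c(rep("heart", 5), rep("lung", 35)))
  enr <- metadata_enrichment(centers, meta)
  p_heart <- enr$p[enr$module == "m1" & enr$label == "heart"]
  expect_equal(p_heart, 1 / choose(40, 5), tolerance = 1e-12)
  expect_true(all(enr$p[enr$module == "m2"] == 1))
  # empty inclusion set warns and is skipped
  centers0 <- rbind(centers, m3 = rep(0, 40))
  expect_warning(enr0 <- metadata_enrichment(centers0, meta), "empty")
  expect_false("m3" %in% enr0$module)
  expect_error(metadata_enrichment(centers, meta[1:10, ]), "cover")
})
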