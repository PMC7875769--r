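# Enhancer-gene link prediction: expression-activity correlation features
# within 1 Mb of the TSS, paired cross-chromosome negatives, a
# gradient-boosted tree classifier, the 5/7 probability threshold, and the
# precision/recall evaluation protocol.

#' Correlation features for enhancer-gene link candidates
#'
#' One candidate per (enhancer, gene) pair whose TSS lies within `window_bp`
#' of the enhancer midpoint; for each mark, the Pearson correlation of gene
#' expression with enhancer signal across the shared biosamples. A
#' correlation undefined because one vector is constant is recorded as 0
#' with `constant_flag = TRUE`.
#'
#' @param expression genes x biosamples matrix.
#' @param signal named list of mark -> (elements x biosamples) signal
#'   matrices.
#' @param tss data.frame: `gene`, `chrom`, `pos`.
#' @param elements data.frame of enhancer intervals: `chrom`, `start`,
#'   `end`, `id`.
#' @param window_bp maximal TSS-midpoint distance (default 1 Mb, inclusive).
#' @return data.table: enhancer, gene, chrom, distance_bp (signed
#'   TSS - midpoint), one `r_<mark>` column per mark, constant_flag.
#' @export
candidate_correlations <- function(expression, signal, tss, elements,
                                   window_bp = 1000000L) {
  tss <- data.table::as.data.table(tss)
  elements <- data.table::as.data.table(elements)
  shared <- intersect(colnames(expression), colnames(signal[[1]]))
  if (length(shared) < 3L) stop("fewer than 3 shared biosamples")
  mid <- (elements$start + elements$end) %/% 2L
  out <- list()
  for (ch in unique(elements$chrom)) {
    ei <- which(elements$chrom == ch)
    gi <- which(tss$chrom == ch & tss$gene %in% rownames(expression))
    if (!length(ei) || !length(gi)) next
    d <- outer(tss$pos[gi], mid[ei], "-")
    pairs <- which(abs(d) <= window_bp, arr.ind = TRUE)
    if (!nrow(pairs)) next
    dt <- data.table::data.table(
      enhancer = elements$id[ei][pairs[, 2]],
      gene = tss$gene[gi][pairs[, 1]],
      chrom = ch,
      distance_bp = d[pairs]
    )
    ex <- t(expression[tss$gene[gi], shared, drop = FALSE])
    const <- rep(FALSE, nrow(dt))
    for (mk in names(signal)) {
      sg <- t(signal[[mk]][elements$id[ei], shared, drop = FALSE])
      sd_e <- apply(ex, 2, stats::sd)
      sd_s <- apply(sg, 2, stats::sd)
      r <- suppressWarnings(stats::cor(ex, sg))
      rv <- r[cbind(pairs[, 1], pairs[, 2])]
      bad <- sd_e[pairs[, 1]] == 0 | sd_s[pairs[, 2]] == 0
      rv[bad] <- 0
      const <- const | bad
      dt[[paste0("r_", mk)]] <- rv
    }
    dt$constant_flag <- const
    out[[ch]] <- dt
  }
  if (!length(out))
    stop("no candidate pairs within the window")
  data.table::rbindlist(out)
}

#' Paired cross-chromosome negative candidates
#'
#' For each positive candidate, one negative is built from the same
#' enhancer and a gene drawn uniformly from a different chromosome; the
#' correlation features are recomputed for the random pairing while the
#' distance feature reuses the paired positive's distance, so the classes
#' cannot be separated on distance alone (`distance = "resample"` instead
#' draws from the positive distance distribution).
#'
#' @param candidates positive candidate table from
#'   [candidate_correlations()].
#' @param expression,signal,tss as in [candidate_correlations()].
#' @param seed RNG seed.
#' @param distance `"paired"` (default) or `"resample"`.
#' @return data.table with the same feature columns as `candidates`.
#' @export
make_negatives <- function(candidates, expression, signal, tss, seed = 1L,
                           distance = c("paired", "resample")) {
  distance <- match.arg(distance)
  tss <- data.table::as.data.table(tss)
  if (length(unique(tss$chrom)) < 2L)
    stop("negatives need genes on at least 2 chromosomes")
  set.seed(derive_seed(seed, "linking"))
  shared <- intersect(colnames(expression), colnames(signal[[1]]))
  neg <- data.table::copy(candidates)
  genes <- tss$gene[tss$gene %in% rownames(expression)]
  gene_chrom <- tss$chrom[match(genes, tss$gene)]
  pick <- vapply(candidates$chrom, function(ch) {
    pool <- which(gene_chrom != ch)
    if (!length(pool)) stop("no genes on a different chromosome")
    pool[sample.int(length(pool), 1L)]
  }, 0L)
  neg$gene <- genes[pick]
  if (distance == "resample")
    neg$distance_bp <- sample(candidates$distance_bp, nrow(neg),
                              replace = TRUE)
  ex <- t(expression[neg$gene, shared, drop = FALSE])
  for (mk in names(signal)) {
    sg <- t(signal[[mk]][neg$enhancer, shared, drop = FALSE])
    r <- vapply(seq_len(nrow(neg)), function(i) {
      if (stats::sd(ex[, i]) == 0 || stats::sd(sg[, i]) == 0) return(0)
      stats::cor(ex[, i], sg[, i])
    }, 0)
    neg[[paste0("r_", mk)]] <- r
  }
  neg
}

link_feature_matrix <- function(dt) {
  rcols <- grep("^r_", names(dt), value = TRUE)
  as.matrix(cbind(dt[, rcols, with = FALSE],
                  abs_distance = abs(dt$distance_bp)))
}

#' Train the enhancer-gene link classifier
#'
#' Gradient-boosted decision trees (binary logistic objective) on the
#' per-mark correlations and the absolute TSS distance, trained on the
#' positive candidates against their paired negatives. Deterministic given
#' the seed (single thread).
#'
#' @param positives,negatives candidate tables with identical feature
#'   columns.
#' @param seed RNG seed.
#' @param nrounds,max_depth,eta boosting hyperparameters (defaults 500
#'   trees of depth 4 at learning rate 0.05).
#' @return a `link_classifier`: list with the fitted booster and the
#'   feature-column names.
#' @export
train_link_classifier <- function(positives, negatives, seed = 1L,
                                  nrounds = 500L, max_depth = 4L,
                                  eta = 0.05) {
  X <- rbind(link_feature_matrix(positives), link_feature_matrix(negatives))
  y <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)))
  if (length(unique(y)) < 2L) stop("degenerate single-class input")
  set.seed(derive_seed(seed, "linking"))
  model <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1,
                  seed = derive_seed(seed, "linking")),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
  structure(list(model = model, features = colnames(X)),
            class = "link_classifier")
}

#' Predict link probabilities for candidates
#'
#' @param classifier a `link_classifier`.
#' @param candidates candidate table with the training feature columns.
#' @return numeric probabilities in \[0, 1\].
#' @export
link_probability <- function(classifier, candidates) {
  X <- link_feature_matrix(candidates)
  if (!identical(colnames(X), classifier$features))
    stop("feature columns do not match the classifier")
  stats::predict(classifier$model, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Emit per-biosample, per-state link predictions
#'
#' One output row per (enhancer, gene, biosample, chromatin state) where
#' the enhancer is active in the biosample; a link is kept iff its
#' probability strictly exceeds `threshold` (default 5/7).
#'
#' @param classifier a `link_classifier`.
#' @param candidates candidate feature table.
#' @param activity binary elements x biosamples matrix (or
#'   `activity_matrix`).
#' @param states elements x biosamples matrix of state mnemonics (NA where
#'   inactive), e.g. the compendium truth states; optional.
#' @param threshold keep cutoff, strict (default `5/7`).
#' @return data.table: enhancer, gene, biosample, state, probability, kept.
#' @export
predict_links <- function(classifier, candidates, activity, states = NULL,
                          threshold = 5 / 7) {
  if (inherits(activity, "activity_matrix")) activity <- activity$A
  prob <- link_probability(classifier, candidates)
  idx <- match(candidates$enhancer, rownames(activity))
  keep <- which(!is.na(idx))
  hits <- which(activity[idx[keep], , drop = FALSE] > 0, arr.ind = TRUE)
  res <- if (nrow(hits)) {
    ci <- keep[hits[, 1]]
    data.table::data.table(
      enhancer = candidates$enhancer[ci],
      gene = candidates$gene[ci],
      biosample = colnames(activity)[hits[, 2]],
      state = if (is.null(states)) NA_character_ else
        states[cbind(idx[ci], hits[, 2])],
      probability = prob[ci]
    )
  } else {
    data.table::data.table(enhancer = character(0), gene = character(0),
                           biosample = character(0), state = character(0),
                           probability = numeric(0))
  }
  res$kept <- res$probability > threshold
  res[order(res$enhancer, res$gene, res$biosample), ]
}

#' Evaluate link predictions against a gold standard
#'
#' For thresholded methods the kept (enhancer, gene) pairs are scored
#' against gold positive and negative pairs; for score-only baselines
#' (`mode = "best_per_enhancer"`, e.g. distance alone) each enhancer
#' contributes only its best-scoring gene as a positive call. Precision is
#' reported as 0 with `undefined_precision = TRUE` when nothing is called.
#'
#' @param predictions data.table with `enhancer`, `gene` and (for the
#'   baseline mode) a `score` column; for thresholded mode only kept rows
#'   should be passed.
#' @param gold_positives,gold_negatives data.frames of (enhancer, gene)
#'   pairs.
#' @param mode `"threshold"` or `"best_per_enhancer"`.
#' @param score_col score column for the baseline mode (higher is better).
#' @return one-row data.table: tp, fp, fn, precision, recall, f1,
#'   undefined_precision.
#' @export
evaluate_links <- function(predictions, gold_positives, gold_negatives,
                           mode = c("threshold", "best_per_enhancer"),
                           score_col = "score") {
  mode <- match.arg(mode)
  if (nrow(gold_positives) == 0L) stop("empty gold-standard set")
  key <- function(d) paste(d$enhancer, d$gene, sep = "\r")
  pos <- unique(key(gold_positives))
  neg <- unique(key(gold_negatives))
  calls <- if (mode == "best_per_enhancer") {
    dt <- data.table::as.data.table(predictions)
    dt <- dt[order(-dt[[score_col]], dt$gene), ]
    unique(key(dt[!duplicated(dt$enhancer), ]))
  } else {
    unique(key(predictions))
  }
  calls <- calls[calls %in% c(pos, neg)]
  tp <- sum(calls %in% pos)
  fp <- sum(calls %in% neg)
  fn <- length(pos) - tp
  undefined <- (tp + fp) == 0L
  precision <- if (undefined) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  data.table::data.table(tp = tp, fp = fp, fn = fn, precision = precision,
                         recall = recall, f1 = f1,
                         undefined_precision = undefined)
}
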