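# Shared numeric and bookkeeping helpers.

#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` marked draws when `n` draws are taken without
#' replacement from a population of `N` objects of which `K` are marked. This
#' is the enrichment p-value used throughout the flat, module, tree and
#' gene-set tests.
#'
#' @param k observed overlap count(s).
#' @param K marked population count(s).
#' @param n draw count(s).
#' @param N population size(s).
#' @return numeric vector of upper-tail probabilities.
#' @export
hyper_tail_p <- function(k, K, n, N) {
  stopifnot(all(k >= 0), all(K <= N), all(n <= N), all(k <= pmin(K, n) + 0L))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Rank-based AUC
#'
#' Area under the ROC curve of `scores` ranking the positive `labels`,
#' computed from the Mann-Whitney statistic. Ties in scores receive average
#' ranks.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) class labels.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("rank_auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Jaccard distance between rows of binary matrix X and rows of binary matrix C.
# Pairs of all-zero vectors get distance 0 (identical empty sets).
jaccard_dist_to_centroids <- function(X, C) {
  inter <- X %*% t(C)
  union <- outer(rowSums(X), rowSums(C), "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  d
}

# Pairwise Jaccard similarity between columns of a binary matrix.
# Two empty columns are identical (similarity 1).
jaccard_sim_columns <- function(A) {
  inter <- crossprod(A)
  cs <- colSums(A)
  union <- outer(cs, cs, "+") - inter
  J <- inter / union
  J[union == 0] <- 1
  J
}

# Jaccard similarity of two index sets.
jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

# md5 of an arbitrary R object via a canonical serialization (version 2,
# no ASCII) written to a tempfile; used for manifest parameter hashes.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# Derived RNG streams: one sub-seed per artifact class so that changing how
# many draws one class consumes cannot perturb another. Offsets are fixed;
# keep results < 2^31 - 1.
derive_seed <- function(master, stream) {
  offsets <- c(
    layout = 101L, signal = 1000003L, states = 2000003L,
    expression = 3000017L, catalog = 4000037L, swaps = 5000011L,
    qc = 6000011L, modules = 7000003L, linking = 8000009L,
    tree = 9000011L, traits = 10000019L, pipeline = 11000081L
  )
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  (as.integer(master) + offsets[[stream]]) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
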