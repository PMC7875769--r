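# Active-enhancer calling from DHS x chromatin states x H3K27ac signal,
# element classification, and k-centroids clustering of the binary activity
# matrix under the Jaccard distance.

#' Match an imputed binarization cutoff to an observed one
#'
#' Returns the imputed-distribution quantile at the exceedance level that
#' the observed cutoff attains in the observed distribution, so that the
#' same fraction of imputed values passes the cutoff. Quantiles use the
#' inverse-ECDF definition (type 1), which makes the mapping exact for
#' identically distributed or rescaled inputs.
#'
#' @param observed,imputed numeric signal samples.
#' @param obs_cutoff observed-scale cutoff (default 2, the -log10 P
#'   activity threshold).
#' @return the matched imputed-scale cutoff.
#' @export
binarization_cutoff <- function(observed, imputed, obs_cutoff = 2) {
  if (length(observed) == 0L || length(imputed) == 0L)
    stop("empty input distribution")
  level <- mean(observed > obs_cutoff)
  unname(stats::quantile(imputed, 1 - level, type = 1, names = FALSE))
}

#' Call active enhancers
#'
#' A DHS element is an active enhancer in a biosample iff (1) it overlaps a
#' segment in one of the enhancer chromatin states in that sample's
#' segmentation and (2) the mean H3K27ac signal over the element extended
#' by `flank_bp` on each side exceeds `signal_threshold`. The mean is
#' weighted by the base-pair overlap of each fixed-width signal bin with
#' the window. Elements active in no biosample are dropped from the matrix
#' and reported in the `dropped` attribute.
#'
#' @param dhs data.frame of DHS intervals (`chrom`, `start`, `end`, `id`;
#'   0-based half-open).
#' @param segmentations named list (by biosample) of dense segmentations:
#'   either data.frames (`chrom`, `start`, `end`, `state`) or named lists
#'   of per-bin state vectors.
#' @param tracks named list (by biosample) of H3K27ac [signal_track()]s.
#' @param states chromatin states that qualify (default the six enhancer
#'   states; pass [PROMOTER_STATES] to call active promoters).
#' @param signal_threshold mean -log10 P signal cutoff (default 2).
#' @param flank_bp flank added on each side of the element (default 100).
#' @param drop_inactive drop all-zero rows (default TRUE).
#' @return an `activity_matrix`: list with binary matrix `A` and mean-signal
#'   matrix `S` (elements x biosamples), the retained `elements` table, and
#'   attribute `dropped` with the ids of all-inactive elements.
#' @export
call_active_enhancers <- function(dhs, segmentations, tracks,
                                  states = ENHANCER_STATES,
                                  signal_threshold = 2, flank_bp = 100L,
                                  drop_inactive = TRUE) {
  dhs <- data.table::as.data.table(dhs)
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(dhs)))
  if (!all(states %in% ALL_STATES))
    stop("unknown state mnemonic: ",
         paste(setdiff(states, ALL_STATES), collapse = ", "))
  samples <- names(segmentations)
  stopifnot(identical(sort(samples), sort(names(tracks))))
  track_chroms <- names(tracks[[1]]$signal)
  if (!all(dhs$chrom %in% track_chroms))
    stop("DHS outside declared chromosomes")
  n <- nrow(dhs)
  A <- matrix(FALSE, n, length(samples), dimnames = list(dhs$id, samples))
  S <- matrix(NA_real_, n, length(samples), dimnames = list(dhs$id, samples))
  for (s in samples) {
    seg <- segmentations[[s]]
    if (is.list(seg) && !is.data.frame(seg)) {
      bad <- setdiff(unique(unlist(seg, use.names = FALSE)), ALL_STATES)
      if (length(bad)) stop("unknown state mnemonic: ", bad[1])
      bp <- tracks[[s]]$bin_bp
      # per-bin vectors: state hit if any overlapped bin is in `states`
      state_hit <- vapply(seq_len(n), function(i) {
        v <- seg[[dhs$chrom[i]]]
        b0 <- dhs$start[i] %/% bp
        b1 <- (dhs$end[i] - 1L) %/% bp
        any(v[(b0 + 1L):(b1 + 1L)] %in% states)
      }, TRUE)
    } else {
      seg <- data.table::as.data.table(seg)
      bad <- setdiff(unique(seg$state), ALL_STATES)
      if (length(bad)) stop("unknown state mnemonic: ", bad[1])
      segq <- seg[seg$state %in% states,
                  list(chrom, s0 = start, s1 = end - 1L)]
      data.table::setkey(segq, chrom, s0, s1)
      q <- data.table::data.table(chrom = dhs$chrom, s0 = dhs$start,
                                  s1 = dhs$end - 1L, idx = seq_len(n))
      ov <- data.table::foverlaps(q, segq, type = "any", nomatch = NULL)
      state_hit <- seq_len(n) %in% ov$idx
    }
    S[, s] <- region_mean_signal(tracks[[s]], dhs$chrom,
                                 dhs$start - flank_bp, dhs$end + flank_bp)
    A[, s] <- state_hit & S[, s] > signal_threshold
  }
  keep <- if (drop_inactive) rowSums(A) > 0 else rep(TRUE, n)
  out <- structure(
    list(A = A[keep, , drop = FALSE] * 1L, S = S[keep, , drop = FALSE],
         elements = dhs[keep, ]),
    class = "activity_matrix"
  )
  attr(out, "dropped") <- dhs$id[!keep]
  out
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d elements x %d biosamples (%.1f%% active)\n",
              nrow(x$A), ncol(x$A), 100 * mean(x$A)))
  invisible(x)
}

#' Classify elements as enhancer, promoter or dyadic
#'
#' An element is an enhancer iff strictly more than 75% of its active
#' occurrences carry enhancer annotations, a promoter under the symmetric
#' rule, and dyadic otherwise (75% exactly is dyadic). Occurrences are
#' per-biosample active calls.
#'
#' @param enhancer_occurrences,promoter_occurrences non-negative counts per
#'   element (named vectors; not both zero for any element).
#' @param cut strict majority fraction (default 0.75).
#' @return data.table: element, both counts, class.
#' @export
classify_elements <- function(enhancer_occurrences, promoter_occurrences,
                              cut = 0.75) {
  stopifnot(length(enhancer_occurrences) == length(promoter_occurrences),
            all(enhancer_occurrences >= 0), all(promoter_occurrences >= 0))
  tot <- enhancer_occurrences + promoter_occurrences
  if (any(tot == 0)) stop("element with zero active occurrences")
  frac <- enhancer_occurrences / tot
  cls <- ifelse(frac > cut, "enhancer",
                ifelse(1 - frac > cut, "promoter", "dyadic"))
  data.table::data.table(
    element = names(enhancer_occurrences) %||%
      as.character(seq_along(enhancer_occurrences)),
    enhancer_occurrences = enhancer_occurrences,
    promoter_occurrences = promoter_occurrences,
    class = cls
  )
}

#' Cluster enhancers into modules (k-centroids under Jaccard distance)
#'
#' Lloyd-style alternation on the binary activity matrix: each element is
#' assigned to the centroid with minimal Jaccard distance
#' `1 - |x AND c| / |x OR c|` (assignment ties broken by lowest module
#' index); centroids are updated to within-module column means and
#' binarized at 0.5 for the distance computation while the real-valued
#' means are retained as interpretable activity frequencies. Initialization
#' is greedy farthest-point: a seeded random first centroid, then the
#' element maximizing the minimal Jaccard distance to those already chosen.
#' Iteration stops when assignments are stable or the mean-distance
#' objective improves by less than `tol`. An emptied module is re-seeded
#' with the element farthest from its current centroid. Like any Lloyd
#' iteration the alternation only finds a local optimum, so `nstart`
#' restarts are run from different seeded first centroids and the solution
#' with the lowest final objective is returned (ties to the earliest
#' restart).
#'
#' @param A binary matrix (elements x biosamples) or an `activity_matrix`.
#' @param k number of modules; must not exceed the number of distinct rows.
#' @param seed RNG seed (initialization is the only stochastic step).
#' @param max_iter,tol convergence controls.
#' @param nstart number of restarts (default 5).
#' @param binary_centroids use binarized centroids in the distance (default
#'   TRUE; FALSE uses a real-valued Jaccard extension
#'   `1 - sum(min) / sum(max)`).
#' @return a `module_set`: list with `k`, `assignment` (named integer),
#'   `centers` (k x biosamples, mean activity in \[0, 1\]), `objective`
#'   trace and iteration count of the winning restart.
#' @export
cluster_modules <- function(A, k, seed = 1L, max_iter = 100L, tol = 1e-6,
                            nstart = 5L, binary_centroids = TRUE) {
  if (inherits(A, "activity_matrix")) A <- A$A
  X <- (A > 0) * 1
  if (nrow(X) == 0L) stop("empty activity matrix")
  n_distinct <- nrow(unique(X))
  if (k > n_distinct)
    stop("k (", k, ") exceeds number of distinct rows (", n_distinct, ")")
  set.seed(derive_seed(seed, "modules"))
  n <- nrow(X)

  dist_fun <- function(C) {
    if (binary_centroids) {
      jaccard_dist_to_centroids(X, (C >= 0.5) * 1)
    } else {
      # real-valued extension: 1 - sum(pmin) / sum(pmax)
      d <- matrix(0, n, nrow(C))
      for (j in seq_len(nrow(C))) {
        mn <- sweep(X, 2, C[j, ], pmin) %*% rep(1, ncol(X))
        mx <- sweep(X, 2, C[j, ], pmax) %*% rep(1, ncol(X))
        dj <- 1 - mn / mx
        dj[mx == 0] <- 0
        d[, j] <- dj
      }
      d
    }
  }

  one_start <- function(first_idx) {
    # greedy farthest-point initialization from the given first centroid
    centers_idx <- first_idx
    mind <- jaccard_dist_to_centroids(X, X[centers_idx, , drop = FALSE])[, 1]
    while (length(centers_idx) < k) {
      nxt <- which.max(mind)  # ties -> lowest index
      centers_idx <- c(centers_idx, nxt)
      mind <- pmin(mind,
                   jaccard_dist_to_centroids(X, X[nxt, , drop = FALSE])[, 1])
    }
    C <- X[centers_idx, , drop = FALSE] * 1
    assignment <- integer(n)
    objective <- numeric(0)
    for (it in seq_len(max_iter)) {
      D <- dist_fun(C)
      new_assign <- max.col(-D, ties.method = "first")
      # re-seed empty modules with the globally worst-fit element
      for (j in which(tabulate(new_assign, k) == 0L)) {
        far <- which.max(D[cbind(seq_len(n), new_assign)])
        C[j, ] <- X[far, ]
        new_assign[far] <- j
      }
      obj <- mean(dist_fun(C)[cbind(seq_len(n), new_assign)])
      stable <- identical(new_assign, assignment)
      converged <- length(objective) > 0 &&
        abs(utils::tail(objective, 1) - obj) < tol
      assignment <- new_assign
      objective <- c(objective, obj)
      for (j in seq_len(k))
        C[j, ] <- colMeans(X[assignment == j, , drop = FALSE])
      if (stable || converged) break
    }
    list(assignment = assignment, centers = C, objective = objective,
         iterations = it)
  }

  firsts <- sample.int(n, min(nstart, n))
  best <- NULL
  for (f in firsts) {
    run <- one_start(f)
    if (is.null(best) ||
        utils::tail(run$objective, 1) < utils::tail(best$objective, 1) - 1e-12)
      best <- run
  }
  assignment <- best$assignment
  names(assignment) <- rownames(X)
  C <- best$centers
  rownames(C) <- sprintf("module%02d", seq_len(k))
  structure(list(k = k, assignment = assignment, centers = C,
                 objective = best$objective, iterations = best$iterations),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> k = %d over %d elements; objective %.4f (%d iter)\n",
              x$k, length(x$assignment), utils::tail(x$objective, 1),
              x$iterations))
  invisible(x)
}

#' Diagonalization column order for a centres matrix
#'
#' Orders the columns of a matrix in \[0, 1\] for heat-map display: columns
#' with a value above `broad_value` in more than `broad_rows` of the rows
#' come first (the broadly active block, ordered by column name), and the
#' remaining columns are sorted by the row index contributing their maximal
#' value, ties broken lexicographically by column name. To diagonalize
#' module centres, pass the transposed centres matrix (modules as columns).
#'
#' @param centers numeric matrix with values in \[0, 1\].
#' @param broad_value,broad_rows broad-block rule (defaults 0.25 and 0.5).
#' @return the column names (or indices when unnamed) in display order.
#' @export
diagonalize <- function(centers, broad_value = 0.25, broad_rows = 0.5) {
  stopifnot(all(centers >= 0 & centers <= 1))
  ids <- colnames(centers) %||% as.character(seq_len(ncol(centers)))
  broad <- colSums(centers > broad_value) > broad_rows * nrow(centers)
  argmax <- apply(centers, 2, which.max)
  rest <- which(!broad)
  c(ids[broad][order(ids[broad])],
    ids[rest][order(argmax[rest], ids[rest])])
}

#' Hypergeometric metadata enrichment of module centres
#'
#' For each module, the biosamples with centre value above
#' `inclusion_threshold` form the included set; for every metadata label
#' (each level of each metadata column), the upper-tail hypergeometric
#' p-value of the label count among included samples versus its overall
#' frequency is computed. Entries with `-log10 p > 2` carry a `reported`
#' flag. Modules with an empty inclusion set are skipped with a warning.
#'
#' @param modules a `module_set` (or a centres matrix, modules x samples).
#' @param metadata data.frame with a `sample` column plus label columns.
#' @param inclusion_threshold centre cutoff (default 0.25).
#' @param report_cut -log10 p cutoff for the `reported` flag (default 2).
#' @return data.table: module, field, label, k, K, n, N, p, neg_log10_p,
#'   reported.
#' @export
metadata_enrichment <- function(modules, metadata,
                                inclusion_threshold = 0.25, report_cut = 2) {
  centers <- if (inherits(modules, "module_set")) modules$centers else modules
  metadata <- data.table::as.data.table(metadata)
  if (!all(colnames(centers) %in% metadata$sample))
    stop("metadata does not cover all biosamples")
  fields <- setdiff(names(metadata), "sample")
  meta <- metadata[match(colnames(centers), metadata$sample), ]
  N <- ncol(centers)
  out <- list()
  for (m in rownames(centers)) {
    inc <- centers[m, ] > inclusion_threshold
    if (!any(inc)) {
      warning("module ", m, " has an empty inclusion set; skipped")
      next
    }
    for (f in fields) {
      labs <- meta[[f]]
      for (lv in unique(labs)) {
        k <- sum(inc & labs == lv)
        K <- sum(labs == lv)
        p <- hyper_tail_p(k, K, sum(inc), N)
        out[[length(out) + 1L]] <- data.table::data.table(
          module = m, field = f, label = lv, k = k, K = K, n = sum(inc),
          N = N, p = p, neg_log10_p = -log10(p), reported = -log10(p) > report_cut)
      }
    }
  }
  data.table::rbindlist(out)
}
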