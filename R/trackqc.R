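# Quality control of imputed vs observed signal tracks: the four standard
# imputation QC metrics, elbow-based low-quality flagging, sample- and
# antibody-swap detection via 3-SD regression residuals, and delta-track
# secondary-reactivity screening.

top_frac_bins <- function(values, frac) {
  n_top <- max(1L, floor(frac * length(values)))
  # rank by signal, ties broken by genomic order
  order(-values, seq_along(values))[seq_len(n_top)]
}

#' Imputation quality metrics for an observed/imputed track pair
#'
#' Computes the genome-wide Pearson correlation, the observed and imputed
#' peak recoveries (percentage of the top-1% bins of one track contained in
#' the top-5% bins of the other) and the AUC with which the imputed signal
#' ranks the top-1% observed bins. Top-x% bin sets are defined by signal
#' rank with ties broken by genomic order.
#'
#' @param observed,imputed [signal_track()]s on identical binnings.
#' @return list with `genomewide_correlation`, `peak_recovery_obs`,
#'   `peak_recovery_imp` (percentages in \[0, 100\]) and `auc`.
#' @export
qc_metrics <- function(observed, imputed) {
  check_same_binning(observed, imputed)
  x <- track_values(observed)
  y <- track_values(imputed)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("all-constant track: correlation undefined")
  top1_obs <- top_frac_bins(x, 0.01)
  top1_imp <- top_frac_bins(y, 0.01)
  top5_obs <- top_frac_bins(x, 0.05)
  top5_imp <- top_frac_bins(y, 0.05)
  list(
    genomewide_correlation = stats::cor(x, y),
    peak_recovery_obs = 100 * mean(top1_obs %in% top5_imp),
    peak_recovery_imp = 100 * mean(top1_imp %in% top5_obs),
    auc = rank_auc(y, seq_along(x) %in% top1_obs)
  )
}

#' Flag low-quality tracks by the elbow in ranked correlations
#'
#' Tracks are sorted by decreasing correlation; the elbow is the first rank
#' at which the drop from the previous value exceeds 5% of that previous
#' value. The elbow track and everything below it are flagged; if no such
#' drop exists, nothing is flagged.
#'
#' @param correlations named numeric vector of per-track correlation
#'   metrics (at least 3).
#' @param rel_change relative drop threshold (default 0.05).
#' @return character vector of flagged track ids (possibly empty).
#' @export
flag_low_quality <- function(correlations, rel_change = 0.05) {
  if (length(correlations) < 3L) stop("need at least 3 tracks")
  if (is.null(names(correlations)))
    names(correlations) <- paste0("track", seq_along(correlations))
  ord <- order(-correlations, names(correlations))
  v <- correlations[ord]
  drops <- v[-length(v)] - v[-1]
  elbow <- which(drops > rel_change * v[-length(v)])
  if (length(elbow) == 0L) return(character(0))
  names(v)[(min(elbow) + 1L):length(v)]
}

# Correlation matrix between two track collections over concatenated bins.
track_cor_matrix <- function(tracks_a, tracks_b) {
  A <- vapply(tracks_a, track_values, numeric(length(track_values(
    tracks_a[[1]]))))
  B <- vapply(tracks_b, track_values, numeric(nrow(A)))
  stats::cor(A, B)
}

track_info <- function(tracks) {
  data.table::data.table(
    id = names(tracks),
    sample = vapply(tracks, `[[`, "", "sample"),
    mark = vapply(tracks, `[[`, "", "mark")
  )
}

# Average correlation of each row of `cm` (observed tracks) to its top-k
# most-correlated columns among `cols`.
avg_topk <- function(cm, cols, k = 10L) {
  if (length(cols) < k) {
    warning("fewer than ", k, " imputed tracks for a mark; using all")
    k <- length(cols)
  }
  apply(cm[, cols, drop = FALSE], 1, function(r)
    mean(sort(r, decreasing = TRUE)[seq_len(k)]))
}

# Outlier scores from an OLS fit of y on one or more covariates: externally
# studentized (leave-one-out) residuals in SD units. Plain residual/SD scoring
# breaks down at desk scale, where a single swapped track is a high-leverage
# point that drags the fitted line through itself; the studentized form is
# the same 3-SD rule made leverage- and masking-robust.
# Several planted anomalies can co-occur in one regression (e.g. an
# antibody-swapped track sits in the sample-swap model of its putative
# mark), so a single fit suffers masking: each outlier inflates the scale
# and drags the line for the others. The scorer therefore peels
# iteratively - remove the worst >threshold point, refit on the clean
# remainder - and finally scores every point against the clean fit
# (externally studentized residuals for kept points, prediction residuals
# over the clean scale for peeled ones).
ols_outlier_scores <- function(X, y, sd_mult = 3, min_keep = 5L) {
  X <- as.matrix(X)
  n <- length(y)
  keep <- seq_len(n)
  fit_on <- function(idx) {
    if (ncol(X) == 0L) stats::lm(y[idx] ~ 1) else
      stats::lm(y[idx] ~ X[idx, , drop = FALSE])
  }
  repeat {
    fit <- fit_on(keep)
    s <- stats::sd(stats::resid(fit))
    if (is.na(s) || s < 1e-12) {
      warning("zero residual variance; no flags")
      return(rep(0, n))
    }
    t <- stats::rstudent(fit)
    t[!is.finite(t)] <- 0
    worst <- which.max(abs(t))
    if (abs(t[worst]) > sd_mult && length(keep) > min_keep) {
      keep <- keep[-worst]
    } else break
  }
  scores <- numeric(n)
  scores[keep] <- t
  out <- setdiff(seq_len(n), keep)
  if (length(out)) {
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    pred <- if (ncol(X) == 0L) rep(co[1], length(out)) else
      co[1] + X[out, , drop = FALSE] %*% co[-1]
    scores[out] <- (y[out] - pred) / stats::sigma(fit)
  }
  scores
}

# Shared engine for the cross-mark outlier detectors. For every observed
# track, computes the average correlation to the top 10 most similar imputed
# tracks of each mark; per ordered mark pair (putative, other), fits an OLS
# line (with a mean-of-remaining-marks covariate absorbing per-sample
# connectivity) over the tracks of the putative mark and scores each track
# by its externally studentized residual. A track is evaluated only against
# its maximal cross-mark average - the candidate true mark - which is where
# a swap or reactivity manifests. When `require_same_deficit` is TRUE, a
# flag additionally requires the track's same-mark average to sit more than
# `sd_mult` SD below its mark's cloud: a swapped track both fits a foreign
# mark too well and its putative mark too poorly.
cross_mark_flags <- function(observed, imputed, kind, sd_mult = 3,
                             require_same_deficit = TRUE) {
  info_o <- track_info(observed)
  info_i <- track_info(imputed)
  cm <- track_cor_matrix(observed, imputed)
  marks <- unique(info_i$mark)
  a <- sapply(marks, function(m) avg_topk(cm, which(info_i$mark == m)))
  if (length(observed) == 1L) a <- matrix(a, 1, dimnames = list(NULL, marks))
  flags <- list()
  for (m in intersect(unique(info_o$mark), marks)) {
    rows <- which(info_o$mark == m)
    if (length(rows) < 3L) next
    cross_marks <- setdiff(marks, m)
    amax <- cross_marks[apply(a[rows, cross_marks, drop = FALSE], 1,
                              which.max)]
    same_dev <- ols_outlier_scores(matrix(nrow = length(rows), ncol = 0),
                                   a[rows, m])
    for (m2 in cross_marks) {
      # covariate: mean cross-mark average over the remaining marks, which
      # absorbs per-sample connectivity. The same-mark average is kept out
      # of the design - a swapped track's collapsed same-mark value would
      # be an extreme-leverage x anchoring the fit - and enters through the
      # separate deficit condition instead.
      others <- setdiff(marks, c(m, m2))
      X <- if (length(others)) {
        matrix(rowMeans(a[rows, others, drop = FALSE]), ncol = 1)
      } else matrix(nrow = length(rows), ncol = 0)
      sc <- ols_outlier_scores(X, a[rows, m2])
      hit <- which(sc > sd_mult & amax == m2 &
                     (!require_same_deficit | same_dev < -sd_mult))
      for (h in hit) {
        flags[[length(flags) + 1L]] <- data.table::data.table(
          track = info_o$id[rows[h]], kind = kind, score_sd = sc[h],
          putative_mark = m, other_mark = m2,
          same_mark_avg = a[rows[h], m], cross_mark_avg = a[rows[h], m2])
      }
    }
  }
  if (length(flags)) data.table::rbindlist(flags) else
    data.table::data.table(track = character(0), kind = character(0),
                           score_sd = numeric(0), putative_mark = character(0),
                           other_mark = character(0),
                           same_mark_avg = numeric(0),
                           cross_mark_avg = numeric(0))
}

#' Detect antibody swaps by cross-mark correlation outliers
#'
#' For each observed track, the average correlation to the top 10 most
#' similar imputed tracks is computed for its putative mark and for every
#' other mark. Per ordered mark pair, the cross-mark average is regressed
#' (OLS with intercept) on the same-mark average over all tracks of the
#' putative mark, and a track is flagged when its studentized residual
#' against its best-matching foreign mark exceeds 3 SD while its own-mark
#' average falls more than 3 SD below the mark's cloud - the compound
#' signature of exchanged antibody labels.
#'
#' @param observed,imputed named lists of [signal_track()]s; imputed should
#'   offer at least 10 tracks per mark.
#' @param sd_mult residual threshold in SD units (default 3).
#' @return data.table flag report: track id, kind, score_sd, the mark pair
#'   and the two correlation summaries supporting the flag.
#' @export
detect_antibody_swaps <- function(observed, imputed, sd_mult = 3) {
  cross_mark_flags(observed, imputed, "antibody_swap", sd_mult,
                   require_same_deficit = TRUE)
}

#' Detect sample swaps by own-sample correlation outliers
#'
#' For each observed track, the correlation to its own biosample's imputed
#' track of the same mark is compared against the average correlation to
#' the top 10 imputed tracks of that mark. Per mark, an OLS line of the
#' own-sample correlation on the top-10 average is fitted, and tracks whose
#' studentized residual falls below -3 SD (an own-sample correlation
#' deficit relative to what their mark-level similarity predicts - the
#' signature of an exchanged sample label) are flagged.
#'
#' @inheritParams detect_antibody_swaps
#' @return data.table flag report (track, kind, score_sd, own-sample and
#'   top-10 correlations).
#' @export
detect_sample_swaps <- function(observed, imputed, sd_mult = 3) {
  info_o <- track_info(observed)
  info_i <- track_info(imputed)
  cm <- track_cor_matrix(observed, imputed)
  flags <- list()
  for (m in unique(info_o$mark)) {
    rows <- which(info_o$mark == m)
    cols <- which(info_i$mark == m)
    if (length(rows) < 3L) next
    own <- vapply(rows, function(r) {
      j <- which(info_i$sample == info_o$sample[r] & info_i$mark == m)
      if (length(j) == 0L) NA_real_ else cm[r, j[1]]
    }, 0)
    top10 <- avg_topk(cm, cols)[rows]
    ok <- !is.na(own)
    if (sum(ok) < 3L) next
    # one-sided: a swapped-in track shows a *deficit* in own-sample
    # correlation relative to what its mark-level similarity predicts
    sc <- ols_outlier_scores(top10[ok], own[ok])
    for (h in which(sc < -sd_mult)) {
      idx <- rows[which(ok)[h]]
      flags[[length(flags) + 1L]] <- data.table::data.table(
        track = info_o$id[idx], kind = "sample_swap",
        score_sd = sc[h], putative_mark = m,
        own_correlation = own[which(ok)[h]],
        top10_same_mark = top10[which(ok)[h]])
    }
  }
  if (length(flags)) data.table::rbindlist(flags) else
    data.table::data.table(track = character(0), kind = character(0),
                           score_sd = numeric(0), putative_mark = character(0),
                           own_correlation = numeric(0),
                           top10_same_mark = numeric(0))
}

#' Delta track: excess observed over rescaled imputed signal
#'
#' The imputed track is quantile-matched onto the observed intensity
#' distribution (robust to monotone intensity distortions, and consistent
#' with observed tracks carrying generally higher intensity), then the
#' per-bin difference is clipped at zero: only excess observed signal is
#' retained, since that is what a secondary antibody reactivity produces.
#'
#' @param observed,imputed [signal_track()]s on identical binnings.
#' @return a [signal_track()] of non-negative per-bin differences (mark
#'   suffixed `.delta`).
#' @export
delta_track <- function(observed, imputed) {
  check_same_binning(observed, imputed)
  x <- track_values(observed)
  y <- track_values(imputed)
  rescaled <- sort(x)[rank(y, ties.method = "first")]
  d <- pmax(x - rescaled, 0)
  sig <- list()
  off <- 0L
  for (ch in names(observed$signal)) {
    n <- length(observed$signal[[ch]])
    sig[[ch]] <- d[(off + 1L):(off + n)]
    off <- off + n
  }
  signal_track(observed$sample, paste0(observed$mark, ".delta"), sig,
               observed$bin_bp)
}

#' Detect secondary antibody reactivities from delta tracks
#'
#' Each delta track is correlated against the imputed compendium; per mark,
#' the average top-10 correlation is computed, and the same per-mark-pair
#' regression / 3-SD residual rule as for antibody swaps flags delta tracks
#' that resemble a non-putative mark too strongly. All-constant delta
#' tracks are skipped with a warning.
#'
#' @param deltas named list of delta [signal_track()]s (putative mark is
#'   taken from the mark field, stripped of a `.delta` suffix).
#' @param imputed named list of imputed [signal_track()]s.
#' @param sd_mult residual threshold in SD units.
#' @return data.table flag report with kind `"secondary_reactivity"`.
#' @export
detect_secondary_reactivity <- function(deltas, imputed, sd_mult = 3) {
  keep <- vapply(deltas, function(t) stats::sd(track_values(t)) > 0, TRUE)
  if (any(!keep))
    warning("skipping all-constant delta track(s): ",
            paste(names(deltas)[!keep], collapse = ", "))
  deltas <- deltas[keep]
  if (length(deltas) == 0L)
    return(data.table::data.table(track = character(0), kind = character(0),
                                  score_sd = numeric(0)))
  deltas <- lapply(deltas, function(t) {
    t$mark <- sub("\\.delta$", "", t$mark)
    t
  })
  # no same-mark-deficit requirement: a clean delta track legitimately has
  # low correlation to its own mark, so only the cross-mark excess counts
  cross_mark_flags(deltas, imputed, "secondary_reactivity", sd_mult,
                   require_same_deficit = FALSE)
}

#' Correlation restricted to a bin mask
#'
#' @param track_a,track_b [signal_track()]s on identical binnings.
#' @param mask integer indices (into the concatenated genomic bin order) or
#'   logical vector selecting the bins to correlate over; at least 3 bins.
#' @param method `"pearson"` or `"spearman"`.
#' @return the correlation over masked bins.
#' @export
restricted_correlation <- function(track_a, track_b, mask,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_same_binning(track_a, track_b)
  x <- track_values(track_a)
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) < 3L) stop("mask must select at least 3 bins")
  stats::cor(x[mask], track_values(track_b)[mask], method = method)
}
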