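# Signal-track container and plain-text genomic I/O (BED, bedGraph, TSV).
# All intervals are 0-based half-open on the declared genome; bedGraph bins
# are fixed-width.

#' Construct a signal track
#'
#' A signal track holds per-bin -log10 P values for one (biosample, mark)
#' pair over a declared genome, at a fixed bin width.
#'
#' @param sample biosample id.
#' @param mark assay / histone-mark name (e.g. `"H3K27ac"`).
#' @param signal named list, one numeric vector of bin values per chromosome.
#' @param bin_bp bin width in base pairs.
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(sample, mark, signal, bin_bp = 200L) {
  stopifnot(is.list(signal), length(names(signal)) == length(signal))
  vals <- unlist(signal, use.names = FALSE)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("signal values must be finite and >= 0")
  structure(
    list(sample = sample, mark = mark, signal = signal,
         bin_bp = as.integer(bin_bp)),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s / %s: %d chrom(s), %d bins @ %d bp\n",
              x$sample, x$mark, length(x$signal),
              sum(lengths(x$signal)), x$bin_bp))
  invisible(x)
}

track_id <- function(track) paste(track$sample, track$mark, sep = ".")

# Concatenated bin values in genomic order (chromosomes in list order).
track_values <- function(track) unlist(track$signal, use.names = FALSE)

check_same_binning <- function(a, b) {
  if (a$bin_bp != b$bin_bp) stop("tracks have different bin widths")
  if (!identical(names(a$signal), names(b$signal)) ||
      !identical(lengths(a$signal), lengths(b$signal)))
    stop("tracks cover different chromosomes or bin counts")
  invisible(TRUE)
}

# Mean signal of `track` over [start, end) on `chrom`, weighted by the
# base-pair overlap of each bin with the window. start/end are clipped to the
# chromosome. Vectorized over windows.
region_mean_signal <- function(track, chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  bp <- track$bin_bp
  out <- numeric(length(start))
  for (ch in unique(chrom)) {
    v <- track$signal[[ch]]
    if (is.null(v)) stop("chromosome not in track: ", ch)
    idx <- which(chrom == ch)
    L <- length(v) * bp
    s <- pmax(start[idx], 0L)
    e <- pmin(end[idx], L)
    if (any(e <= s)) stop("window outside chromosome on ", ch)
    b0 <- s %/% bp
    b1 <- (e - 1L) %/% bp
    acc <- numeric(length(idx))
    for (off in 0:max(b1 - b0)) {
      b <- b0 + off
      live <- b <= b1
      if (!any(live)) break
      ov <- pmin(e, (b + 1) * bp) - pmax(s, b * bp)
      ov[!live] <- 0
      acc <- acc + ov * v[pmin(b, length(v) - 1L) + 1L] * live
    }
    out[idx] <- acc / (e - s)
  }
  out
}

#' Write a signal track as bedGraph
#'
#' Adjacent equal-valued bins are merged into single records; coordinates are
#' 0-based half-open.
#'
#' @param track a [signal_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  bp <- track$bin_bp
  recs <- lapply(names(track$signal), function(ch) {
    v <- track$signal[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths) * bp
    starts <- ends - r$lengths * bp
    data.table::data.table(chrom = ch, start = starts, end = ends,
                           value = signif(r$values, 6))
  })
  data.table::fwrite(data.table::rbindlist(recs), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a fixed-bin bedGraph into a signal track
#'
#' @param path bedGraph file.
#' @param sample,mark track identity.
#' @param bin_bp bin width; records are expanded back to per-bin values.
#' @param genome data.frame with columns `chrom`, `length_bp`.
#' @export
read_bedgraph <- function(path, sample, mark, bin_bp, genome) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  sig <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    v <- numeric(genome$length_bp[i] %/% bin_bp)
    d <- dt[dt$chrom == ch, ]
    if (nrow(d)) {
      for (j in seq_len(nrow(d))) {
        v[(d$start[j] %/% bin_bp + 1L):(d$end[j] %/% bin_bp)] <- d$value[j]
      }
    }
    v
  })
  names(sig) <- genome$chrom
  signal_track(sample, mark, sig, bin_bp)
}

#' Write intervals as BED
#'
#' @param dt data.frame with `chrom`, `start`, `end` and optionally `id`
#'   (written in the BED name field) plus `score`.
#' @param path output file.
#' @export
write_bed <- function(dt, path) {
  cols <- intersect(c("chrom", "start", "end", "id", "score"), names(dt))
  data.table::fwrite(data.table::as.data.table(dt)[, cols, with = FALSE],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED file; first three columns chrom/start/end, optional
#'   fourth column stored as `id`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  nm <- c("chrom", "start", "end", "id", "score")[seq_len(min(ncol(dt), 5L))]
  data.table::setnames(dt, seq_along(nm), nm)
  dt
}

#' Write a per-sample dense chromatin-state segmentation as BED
#'
#' @param states named list, one character vector of per-bin state mnemonics
#'   per chromosome.
#' @param bin_bp bin width.
#' @param path output file.
#' @export
write_segmentation <- function(states, bin_bp, path) {
  recs <- lapply(names(states), function(ch) {
    r <- rle(states[[ch]])
    ends <- cumsum(r$lengths) * bin_bp
    data.table::data.table(chrom = ch, start = ends - r$lengths * bin_bp,
                           end = ends, state = r$values)
  })
  data.table::fwrite(data.table::rbindlist(recs), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a dense segmentation BED
#'
#' @param path BED file with columns chrom, start, end, state.
#' @export
read_segmentation <- function(path) {
  data.table::fread(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "state"))
}
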