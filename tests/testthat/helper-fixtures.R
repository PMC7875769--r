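# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a small default-condition compendium shared across module tests
small_compendium <- function() {
  fixture("small_compendium", function() {
    cfg <- synth_config(seed = 42)
    comp <- generate_compendium(cfg)
    act <- call_active_enhancers(comp$dhs, comp$segmentations, comp$tracks)
    list(cfg = cfg, comp = comp, act = act)
  })
}

make_track <- function(values, sample = "s1", mark = "H3K27ac",
                       bin_bp = 200L) {
  signal_track(sample, mark, list(chrS1 = values), bin_bp)
}

# catalog row constructor for pruning / enrichment tests
make_catalog <- function(chrom, pos, pvalue = NULL, trait = "t1",
                         pubmed_id = 1L, sample_size = 20000L) {
  n <- length(pos)
  data.table::data.table(
    trait = rep_len(trait, n), pubmed_id = rep_len(pubmed_id, n),
    chrom = rep_len(chrom, n), pos = pos,
    pvalue = pvalue %||% rep(1e-10, n),
    sample_size = rep_len(sample_size, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

track_values_test <- function(track) unlist(track$signal, use.names = FALSE)

# delta tracks for every observed/imputed pair of a QC compendium
qc_deltas <- function(qcc) {
  out <- lapply(names(qcc$observed), function(id)
    delta_track(qcc$observed[[id]], qcc$imputed[[id]]))
  names(out) <- names(qcc$observed)
  out
}

# exact upper-tail hypergeometric by explicit binomial-coefficient
# enumeration in log space - the independent oracle for every
# enrichment p-value in the package
oracle_hyper_tail <- function(k, K, n, N) {
  i <- seq(max(k, 0), min(K, n))
  if (length(i) == 0L) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
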