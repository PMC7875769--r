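#' @import data.table
#' @importFrom stats cor sd lm resid p.adjust phyper quantile rnorm runif
#'   rgamma rexp wilcox.test predict setNames
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c(
  "end", "start", "id", "kind", "samples", "module", "study", "usnp_idx",
  "p_bh", "significant", "sample_size", "n_kept", "set", "N", "tissue",
  "p_hyper", "bin", "nshare", "enhancer", "gene", "biosample", "chrom",
  "s0", "s1", "trait", "pubmed_id", "pvalue", "pos", "size", "newd"
))
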