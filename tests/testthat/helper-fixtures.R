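# Small simulation configurations and hand-built tables shared by tests.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 400L, n_proteins = 200L, n_per_group = 4L,
         frac_de = 0.1, effect_log2fc = 1, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# One-row differential table in the shared layer schema.
dt_row <- function(feature, log2fc, p_adj, layer = "rna", timepoint = 35L,
                   detected = TRUE) {
  data.frame(feature = feature, layer = layer, timepoint = timepoint,
             log2fc = log2fc, p_raw = p_adj, p_adj = p_adj,
             mean_fpkm = NA_real_, detected = detected,
             stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg by the sorted min-cummin formula,
# independent of stats::p.adjust.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Exact upper-tail ORA p by exhaustive enumeration of every signature
# draw of size n from a universe of size N with K marked elements.
ora_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)  # marked elements are 1..K
  mean(overlaps >= k)
}
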