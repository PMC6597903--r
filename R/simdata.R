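#' Simulation configuration for a two-genotype, two-timepoint dual-omics study
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' a control vs mutant genotype contrast assayed by bulk RNA-seq and
#' TMT-10plex proteomics at two culture ages (35 and 56 days in vitro),
#' with a configurable fraction of genes carrying planted differential
#' effects concentrated in designated gene sets.
#'
#' @param n_genes Number of genes. The default mirrors the scale of a
#'   well-powered neuronal bulk RNA-seq experiment (~16k detected genes).
#' @param n_proteins Number of quantified proteins; proteins are the first
#'   `n_proteins` gene symbols, so the gene--protein join is deterministic.
#'   Default mirrors ~10.5k proteins per TMT set.
#' @param n_per_group Samples per genotype per timepoint (2--5; the protein
#'   layer packs both groups of one timepoint into a single 10-plex set).
#' @param frac_de Fraction of genes carrying a true differential effect
#'   (0 gives a global null).
#' @param planted_sets Character vector of gene-set names that
#'   [build_genesets()] will enrich for the differential genes.
#' @param effect_log2fc Absolute log2 fold change of every planted effect
#'   (sign randomized per gene).
#' @param nb_dispersion Negative-binomial dispersion `alpha` of the count
#'   layer (variance `mu + alpha * mu^2`).
#' @param compression_factor Multiplicative attenuation of the true log2
#'   fold change as observed in the protein layer, emulating isobaric
#'   reporter-ion ratio compression. Default `1/1.4`, the reciprocal of
#'   the conventional correction factor.
#' @param libsize_cv Coefficient of variation of the true library size
#'   factors.
#' @param channel_sd Standard deviation (log2 scale) of per-channel
#'   multiplicative offsets in the protein layer; makes channel-median
#'   normalization non-trivial.
#' @param noise_sd Residual log2-scale Gaussian noise of protein
#'   intensities.
#' @param seed Integer master seed; each layer derives its own RNG stream
#'   from it by a fixed offset, so adding one layer never perturbs the
#'   draws of another.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, n_proteins = 250, seed = 7)
sim_config <- function(n_genes = 16000L,
                       n_proteins = 10500L,
                       n_per_group = 5L,
                       frac_de = 0.1,
                       planted_sets = character(),
                       effect_log2fc = 1,
                       nb_dispersion = 0.05,
                       compression_factor = 1 / 1.4,
                       libsize_cv = 0.15,
                       channel_sd = 0.5,
                       noise_sd = 0.25,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_proteins <- as.integer(n_proteins)
  n_per_group <- as.integer(n_per_group)
  seed <- as.integer(seed)
  if (is.na(n_genes) || n_genes < 10L)
    stop("configuration error: n_genes must be an integer >= 10")
  if (is.na(n_proteins) || n_proteins < 1L || n_proteins > n_genes)
    stop("configuration error: n_proteins must lie in [1, n_genes]")
  if (is.na(n_per_group) || n_per_group < 2L || n_per_group > 5L)
    stop("configuration error: n_per_group must lie in [2, 5] (10-plex limit)")
  if (!is.numeric(frac_de) || frac_de < 0 || frac_de >= 1)
    stop("configuration error: frac_de must lie in [0, 1)")
  if (!is.numeric(effect_log2fc) || effect_log2fc < 0)
    stop("configuration error: effect_log2fc must be >= 0")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop("configuration error: nb_dispersion must be > 0")
  if (!is.numeric(compression_factor) ||
      compression_factor <= 0 || compression_factor > 1)
    stop("configuration error: compression_factor must lie in (0, 1]")
  if (!is.numeric(libsize_cv) || libsize_cv < 0)
    stop("configuration error: libsize_cv must be >= 0")
  if (!is.numeric(channel_sd) || channel_sd < 0)
    stop("configuration error: channel_sd must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("configuration error: noise_sd must be >= 0")
  if (is.na(seed)) stop("configuration error: seed must be a finite integer")
  structure(
    list(n_genes = n_genes, n_proteins = n_proteins,
         n_per_group = n_per_group, frac_de = frac_de,
         planted_sets = as.character(planted_sets),
         effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
         compression_factor = compression_factor, libsize_cv = libsize_cv,
         channel_sd = channel_sd, noise_sd = noise_sd, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_proteins, "proteins,",
      x$n_per_group, "per group per timepoint;",
      sprintf("frac_de=%g, effect=%g log2FC, seed=%d", x$frac_de,
              x$effect_log2fc, x$seed), "\n")
  invisible(x)
}

sim_gene_ids <- function(n_genes) sprintf("G%05d", seq_len(n_genes))

# Fixed RNG stream offsets per layer (counts / intensities / gene sets).
.stream_counts <- 101L
.stream_intensities <- 202L
.stream_genesets <- 303L

#' Simulate the RNA count layer with planted differential effects
#'
#' Counts are negative binomial with mean
#' `baseline_i * size_factor_j * 2^(log2FC_i)` in mutant samples and
#' variance `mu + alpha * mu^2`. Baseline expression is log-normal, gene
#' lengths are log-uniform on \[500, 20000\] bp so the FPKM detection
#' filter is exercised, and library size factors are log-normal with the
#' configured coefficient of variation (normalized to geometric mean 1).
#' Planted genes keep the same effect at both timepoints, emulating a
#' persistent genotype effect.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `counts` (a `count_matrix`, see
#'   [count_matrix()]) and `truth` (a `sim_truth`: `de_features` data frame
#'   of `feature`, `log2fc` applying to both timepoints and, attenuated by
#'   `compression_factor`, to the protein layer; `enriched_sets`;
#'   `size_factors`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + .stream_counts)
  g <- cfg$n_genes
  ids <- sim_gene_ids(g)
  lengths_bp <- round(10 ^ stats::runif(g, log10(500), log10(20000)))
  baseline <- exp(stats::rnorm(g, log(80), 1.6))

  n_de <- round(cfg$frac_de * g)
  de_idx <- if (n_de > 0) sort(sample.int(g, n_de)) else integer()
  lfc <- numeric(g)
  if (n_de > 0)
    lfc[de_idx] <- cfg$effect_log2fc * sample(c(-1, 1), n_de, replace = TRUE)

  np <- cfg$n_per_group
  samples <- expand.grid(replicate = seq_len(np),
                         genotype = c("control", "mutant"),
                         timepoint = c(35L, 56L),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%02d_d%02d", samples$genotype,
                               samples$replicate, samples$timepoint)
  samples <- samples[, c("sample_id", "genotype", "timepoint")]
  ns <- nrow(samples)

  sdlog <- sqrt(log(1 + cfg$libsize_cv^2))
  sf <- exp(stats::rnorm(ns, 0, sdlog))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- samples$sample_id

  is_mut <- as.numeric(samples$genotype == "mutant")
  mu <- (baseline * 2 ^ outer(lfc, is_mut)) * rep(sf, each = g)
  counts <- matrix(stats::rnbinom(g * ns, mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = g, dimnames = list(ids, samples$sample_id))

  truth <- structure(
    list(de_features = data.frame(feature = ids[de_idx],
                                  log2fc = lfc[de_idx],
                                  stringsAsFactors = FALSE),
         enriched_sets = cfg$planted_sets,
         size_factors = sf),
    class = "sim_truth"
  )
  list(counts = count_matrix(counts, lengths_bp, samples), truth = truth)
}

#' Simulate the TMT protein intensity layer
#'
#' One 10-plex set per timepoint (both genotypes of that timepoint in one
#' set). On the log2 scale each intensity is
#' `baseline + channel_effect + compression_factor * log2FC * I(mutant) + noise`:
#' channels carry distinct multiplicative offsets so channel-median
#' normalization is non-trivial, and the planted effect is attenuated by
#' the configured ratio-compression factor. Proteins are the first
#' `n_proteins` gene symbols of the same configuration.
#'
#' @param cfg A [sim_config()].
#' @param truth The `sim_truth` returned by [simulate_counts()] for the
#'   same `cfg`.
#' @return An [intensity_matrix()].
#' @export
simulate_intensities <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  ids <- sim_gene_ids(cfg$n_genes)
  if (!all(truth$de_features$feature %in% ids))
    stop("consistency error: truth features do not match cfg gene symbols")
  set.seed(cfg$seed + .stream_intensities)

  p <- cfg$n_proteins
  gene_symbols <- ids[seq_len(p)]
  protein_ids <- sprintf("P%05d", seq_len(p))

  lfc <- stats::setNames(numeric(p), gene_symbols)
  hit <- intersect(truth$de_features$feature, gene_symbols)
  lfc[hit] <- truth$de_features$log2fc[match(hit, truth$de_features$feature)]

  np <- cfg$n_per_group
  channels <- expand.grid(replicate = seq_len(np),
                          genotype = c("control", "mutant"),
                          timepoint = c(35L, 56L),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  channels$tmt_set <- sprintf("set_d%02d", channels$timepoint)
  channels$channel_id <- sprintf("tmt%02d_%s_%02d", channels$timepoint,
                                 substr(channels$genotype, 1, 3),
                                 channels$replicate)
  channels <- channels[, c("channel_id", "genotype", "timepoint", "tmt_set")]
  nc <- nrow(channels)

  baseline <- stats::rnorm(p, 20, 2)
  channel_effect <- stats::rnorm(nc, 0, cfg$channel_sd)
  is_mut <- as.numeric(channels$genotype == "mutant")
  log2i <- outer(baseline, channel_effect, "+") +
    cfg$compression_factor * outer(lfc, is_mut) +
    matrix(stats::rnorm(p * nc, 0, cfg$noise_sd), nrow = p)
  intens <- 2 ^ log2i
  dimnames(intens) <- list(protein_ids, channels$channel_id)
  intensity_matrix(intens, protein_ids, gene_symbols, channels)
}

#' Build a gene-set collection with planted enrichment
#'
#' Planted sets (named in `cfg$planted_sets`) draw at least
#' `planted_frac` of their members from the truly differential genes;
#' decoy sets draw uniformly from all genes.
#'
#' @param cfg A [sim_config()] whose `planted_sets` names the enriched
#'   sets.
#' @param truth The matching `sim_truth`.
#' @param n_sets Total number of sets (planted + decoys).
#' @param set_size_range Integer `c(min, max)` of set sizes.
#' @param planted_frac Fraction of a planted set's members drawn from the
#'   differential genes (default 0.6).
#' @return A [geneset_collection()].
#' @export
build_genesets <- function(cfg, truth, n_sets = 51L,
                           set_size_range = c(15L, 25L),
                           planted_frac = 0.6) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  n_sets <- as.integer(n_sets)
  if (n_sets < 2L) stop("configuration error: n_sets must be >= 2")
  if (length(cfg$planted_sets) >= n_sets)
    stop("configuration error: need at least one decoy set")
  set_size_range <- as.integer(set_size_range)
  if (length(set_size_range) != 2L || any(set_size_range < 2L) ||
      set_size_range[1] > set_size_range[2])
    stop("configuration error: invalid set_size_range")
  if (set_size_range[2] > cfg$n_genes)
    stop("configuration error: set size exceeds n_genes")
  set.seed(cfg$seed + .stream_genesets)

  genes <- sim_gene_ids(cfg$n_genes)
  de <- truth$de_features$feature
  non_de <- setdiff(genes, de)
  n_planted <- length(cfg$planted_sets)
  nm <- c(cfg$planted_sets,
          sprintf("DECOY_%02d", seq_len(n_sets - n_planted)))
  sizes <- set_size_range[1] +
    sample.int(set_size_range[2] - set_size_range[1] + 1L, n_sets,
               replace = TRUE) - 1L
  sets <- vector("list", n_sets)
  names(sets) <- nm
  for (i in seq_len(n_sets)) {
    if (i <= n_planted) {
      k_de <- ceiling(planted_frac * sizes[i])
      if (k_de > length(de))
        stop("configuration error: not enough differential genes to plant set '",
             nm[i], "'")
      sets[[i]] <- c(sample(de, k_de), sample(non_de, sizes[i] - k_de))
    } else {
      sets[[i]] <- sample(genes, sizes[i])
    }
  }
  desc <- stats::setNames(
    c(rep("planted", n_planted), rep("decoy", n_sets - n_planted)), nm)
  geneset_collection(sets, desc)
}
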