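#' Pipeline configuration
#'
#' Bundles the simulation conditions and every analysis threshold of the
#' integrated workflow. All randomness flows from the seeds held here;
#' no stage consults global RNG state it did not seed itself.
#'
#' @param sim A [sim_config()].
#' @param alpha FDR threshold declaring a table entry significant in the
#'   cascade (default 0.05).
#' @param fc_min Linear fold-change threshold of the enrichment input
#'   signature (default 1.5).
#' @param fpkm_min RNA detection threshold (default 0.5, strict `>`).
#' @param compression_factor Multiplier applied to protein-sourced log2
#'   fold changes (default 1.4).
#' @param fallback Cascade fallback mode, `"carry_gene35"` or
#'   `"exclude"`.
#' @param n_sets,set_size_range,planted_frac Gene-set collection layout
#'   (see [build_genesets()]).
#' @param n_perm Permutations of the self-contained enrichment member.
#' @param enrich_seed Seed of the permutation stream.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            alpha = 0.05, fc_min = 1.5, fpkm_min = 0.5,
                            compression_factor = 1.4,
                            fallback = "carry_gene35",
                            n_sets = 51L, set_size_range = c(15L, 25L),
                            planted_frac = 0.6,
                            n_perm = 999L, enrich_seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  if (alpha <= 0 || fc_min < 1 || fpkm_min < 0 || compression_factor <= 0 ||
      n_perm < 99)
    stop("pipeline_config: thresholds out of range")
  fallback <- match.arg(fallback, c("carry_gene35", "exclude"))
  structure(list(sim = sim, alpha = alpha, fc_min = fc_min,
                 fpkm_min = fpkm_min,
                 compression_factor = compression_factor,
                 fallback = fallback, n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 planted_frac = planted_frac, n_perm = as.integer(n_perm),
                 enrich_seed = as.integer(enrich_seed)),
            class = "pipeline_config")
}

.pipeline_keys <- c("sim", "alpha", "fc_min", "fpkm_min",
                    "compression_factor", "fallback", "n_sets",
                    "set_size_range", "planted_frac", "n_perm",
                    "enrich_seed")

#' Read / write a pipeline configuration as YAML
#'
#' The file holds the fields of [pipeline_config()] with the simulation
#' conditions nested under `sim`. Unknown keys are rejected, and a
#' write--read round trip reproduces the configuration exactly.
#'
#' @param path YAML file path.
#' @name pipeline_config_io
NULL

#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), .pipeline_keys)
  if (length(unknown))
    stop("read_pipeline_config: unknown key(s): ",
         paste(unknown, collapse = ", "))
  sim_args <- y$sim
  if (!is.null(sim_args)) {
    unknown <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(unknown))
      stop("read_pipeline_config: unknown sim key(s): ",
           paste(unknown, collapse = ", "))
  }
  args <- y[setdiff(names(y), "sim")]
  args$sim <- do.call(sim_config, as.list(sim_args))
  do.call(pipeline_config, args)
}

#' @rdname pipeline_config_io
#' @param cfg A [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  y <- unclass(cfg)
  y$sim <- unclass(y$sim)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' Run the full simulated dual-omics pipeline
#'
#' Executes simulate, RNA differential expression (both timepoints),
#' protein differential abundance (both timepoints), integration and
#' ensemble enrichment, writing every table plus a machine-readable run
#' manifest (thresholds, seeds, md5 of every artifact) to `out_dir`.
#' The same configuration always yields byte-identical artifacts.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory tables (`counts`,
#'   `intensities`, `truth`, `genesets`, `de` list of four tables,
#'   `integrated`, `enrichment`) and the `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- run_stage("simulate", {
    sc <- simulate_counts(cfg$sim)
    list(counts = sc$counts, truth = sc$truth,
         intensities = simulate_intensities(cfg$sim, sc$truth),
         genesets = build_genesets(cfg$sim, sc$truth, n_sets = cfg$n_sets,
                                   set_size_range = cfg$set_size_range,
                                   planted_frac = cfg$planted_frac))
  })
  write_counts(sim$counts, pth("counts.tsv"))
  write_intensities(sim$intensities, pth("intensities.tsv"))
  write_sample_sheet(sim$counts, sim$intensities, pth("samples.tsv"))
  write_gmt(sim$genesets, pth("sets.gmt"))
  jsonlite::write_json(
    list(de_features = sim$truth$de_features,
         enriched_sets = sim$truth$enriched_sets,
         size_factors = as.list(sim$truth$size_factors)),
    pth("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  de <- list(
    rna35 = run_stage("rnaseq_35",
      nb_differential(sim$counts, 35L, fpkm_min = cfg$fpkm_min)),
    rna56 = run_stage("rnaseq_56",
      nb_differential(sim$counts, 56L, fpkm_min = cfg$fpkm_min)),
    prot35 = run_stage("proteomics_35",
      protein_differential(sim$intensities, 35L)),
    prot56 = run_stage("proteomics_56",
      protein_differential(sim$intensities, 56L)))
  write_differential(de$rna35, pth("de_rna_35.tsv"))
  write_differential(de$rna56, pth("de_rna_56.tsv"))
  write_differential(de$prot35, pth("de_protein_35.tsv"))
  write_differential(de$prot56, pth("de_protein_56.tsv"))

  integrated <- run_stage("integrate",
    integrate_tables(de$prot35, de$prot56, de$rna35, de$rna56,
                     alpha = cfg$alpha, fallback = cfg$fallback,
                     factor = cfg$compression_factor,
                     p_max = cfg$alpha, fc_min = cfg$fc_min))
  write_tsv(integrated, pth("integrated.tsv"))

  enrichment <- run_stage("enrich",
    enrich_all(integrated, sim$genesets, n_perm = cfg$n_perm,
               seed = cfg$enrich_seed))
  write_tsv(enrichment, pth("enrichment.tsv"))

  files <- c("counts.tsv", "intensities.tsv", "samples.tsv", "sets.gmt",
             "truth.json", "de_rna_35.tsv", "de_rna_56.tsv",
             "de_protein_35.tsv", "de_protein_56.tsv", "integrated.tsv",
             "enrichment.tsv")
  manifest <- list(
    thresholds = list(alpha = cfg$alpha, fc_min = cfg$fc_min,
                      fpkm_min = cfg$fpkm_min,
                      compression_factor = cfg$compression_factor,
                      fallback = cfg$fallback, n_perm = cfg$n_perm),
    seeds = list(sim = cfg$sim$seed, enrich = cfg$enrich_seed),
    md5 = as.list(tools::md5sum(vapply(files, pth, character(1)))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(sim, list(de = de, integrated = integrated,
                        enrichment = enrichment, manifest = manifest,
                        out_dir = out_dir)))
}
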