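#' Gene-level count matrix with lengths and sample metadata
#'
#' Lightweight container for the RNA layer: an integer matrix of counts
#' (genes x samples), per-gene annotated lengths in bp, and a sample sheet
#' assigning genotype and timepoint.
#'
#' @param counts Non-negative integer matrix, rows named by gene symbol.
#' @param lengths_bp Positive per-gene lengths (bp), same order as rows.
#' @param samples Data frame with columns `sample_id`, `genotype`
#'   (`control`/`mutant`), `timepoint` (35/56), in column order of
#'   `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths_bp, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("count_matrix: rows must be uniquely named by gene symbol")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers")
  if (length(lengths_bp) != nrow(counts) || any(lengths_bp < 1))
    stop("count_matrix: lengths_bp must be >= 1, one per gene")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "timepoint")
  if (!all(req %in% names(samples)))
    stop("count_matrix: sample sheet needs columns ",
         paste(req, collapse = ", "))
  if (nrow(samples) != ncol(counts))
    stop("count_matrix: one sample-sheet row per count column required")
  if (!all(samples$genotype %in% c("control", "mutant")))
    stop("count_matrix: genotype must be 'control' or 'mutant'")
  samples$timepoint <- as.integer(samples$timepoint)
  if (!all(samples$timepoint %in% c(35L, 56L)))
    stop("count_matrix: timepoint must be 35 or 56")
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts,
                 lengths_bp = stats::setNames(as.numeric(lengths_bp),
                                              rownames(counts)),
                 samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; timepoints", paste(sort(unique(x$samples$timepoint)),
                                   collapse = "/"), "\n")
  invisible(x)
}

#' Protein intensity matrix for TMT channels
#'
#' Container for the protein layer: positive reporter intensities
#' (proteins x channels), a protein-to-gene-symbol mapping, and channel
#' metadata. Zeros are treated as missing downstream.
#'
#' @param intensities Positive numeric matrix, proteins x channels.
#' @param protein_ids Unique protein accessions, one per row.
#' @param gene_symbols Gene symbol per protein (may repeat).
#' @param channels Data frame with columns `channel_id`, `genotype`,
#'   `timepoint`, `tmt_set`; at most 10 channels per TMT set.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(intensities, protein_ids, gene_symbols, channels) {
  intensities <- as.matrix(intensities)
  if (length(protein_ids) != nrow(intensities) ||
      anyDuplicated(protein_ids))
    stop("intensity_matrix: protein_ids must be unique, one per row")
  if (length(gene_symbols) != nrow(intensities))
    stop("intensity_matrix: one gene symbol per protein required")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensity_matrix: intensities must be positive (0/NA = missing)")
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  req <- c("channel_id", "genotype", "timepoint", "tmt_set")
  if (!all(req %in% names(channels)))
    stop("intensity_matrix: channel sheet needs columns ",
         paste(req, collapse = ", "))
  if (nrow(channels) != ncol(intensities))
    stop("intensity_matrix: one channel row per intensity column required")
  if (any(table(channels$tmt_set) > 10L))
    stop("intensity_matrix: more than 10 channels in a TMT set")
  channels$timepoint <- as.integer(channels$timepoint)
  rownames(intensities) <- protein_ids
  colnames(intensities) <- channels$channel_id
  structure(list(intensities = intensities,
                 protein_ids = as.character(protein_ids),
                 gene_symbols = as.character(gene_symbols),
                 channels = channels),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "channels in",
      length(unique(x$channels$tmt_set)), "TMT set(s)\n")
  invisible(x)
}

#' Named collection of gene sets
#'
#' @param sets Named list of character vectors of member gene symbols;
#'   names unique, members unique and non-empty within each set.
#' @param description Optional per-set description (named or in order).
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, description = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("geneset_collection: sets must be a uniquely named list")
  sets <- lapply(sets, as.character)
  if (any(vapply(sets, length, 0L) == 0L))
    stop("geneset_collection: empty gene set")
  if (any(vapply(sets, anyDuplicated, 0L) > 0L))
    stop("geneset_collection: duplicate members within a set")
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    description <- stats::setNames(as.character(description), names(sets))
  }
  structure(list(sets = sets, description = description),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  sz <- vapply(x$sets, length, 0L)
  cat("geneset_collection:", length(x$sets), "sets, sizes",
      min(sz), "-", max(sz), "\n")
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$sets)
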