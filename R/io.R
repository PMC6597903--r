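#' Read a GMT gene-set file
#'
#' Tab-delimited, one set per line: name, description, member symbols.
#' Duplicate members within a set are removed with a warning; empty
#' lines are skipped; a line with fewer than three fields or a repeated
#' set name is an error naming the line.
#'
#' @param path File path.
#' @return A [geneset_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop("read_gmt: line ", i, " has fewer than 3 fields")
    nm <- f[1]
    if (nm %in% names(sets))
      stop("read_gmt: duplicate set name '", nm, "' at line ", i)
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("read_gmt: duplicate members in set '", nm, "' deduplicated")
      members <- unique(members)
    }
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  geneset_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [geneset_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  desc <- collection$description
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, desc[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Write / read the RNA count matrix
#'
#' TSV with first column `gene_id`, second `length_bp`, then one column
#' per sample.
#'
#' @param x A [count_matrix()].
#' @param path File path.
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts),
                   length_bp = unname(x$lengths_bp), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname counts_io
#' @param samples Sample sheet data frame (as from [read_sample_sheet()])
#'   restricted to the RNA layer's samples.
#' @export
read_counts <- function(path, samples) {
  df <- read_tsv_strict(path, c("gene_id", "length_bp"))
  counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "length_bp")),
                         drop = FALSE])
  rownames(counts) <- df$gene_id
  counts <- counts[, samples$sample_id, drop = FALSE]
  count_matrix(counts, df$length_bp, samples)
}

#' Write / read the TMT intensity matrix
#'
#' TSV with columns `protein_id`, `gene_symbol`, then one column per
#' channel.
#'
#' @param x An [intensity_matrix()].
#' @param path File path.
#' @name intensities_io
NULL

#' @rdname intensities_io
#' @export
write_intensities <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(protein_id = x$protein_ids, gene_symbol = x$gene_symbols,
                   x$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname intensities_io
#' @param channels Channel sheet data frame with `channel_id`,
#'   `genotype`, `timepoint`, `tmt_set`.
#' @export
read_intensities <- function(path, channels) {
  df <- read_tsv_strict(path, c("protein_id", "gene_symbol"))
  m <- as.matrix(df[, setdiff(names(df), c("protein_id", "gene_symbol")),
                    drop = FALSE])
  m <- m[, channels$channel_id, drop = FALSE]
  intensity_matrix(m, df$protein_id, df$gene_symbol, channels)
}

#' Write / read the sample sheet
#'
#' One row per measurement unit across both layers: `sample_id`,
#' `genotype`, `timepoint`, `layer` (`rna`/`protein`), `channel`
#' (TMT set id for protein rows, empty for RNA).
#'
#' @param counts A [count_matrix()] supplying the RNA rows.
#' @param intensities An [intensity_matrix()] supplying protein rows
#'   (optional).
#' @param path File path.
#' @name sample_sheet_io
NULL

#' @rdname sample_sheet_io
#' @export
write_sample_sheet <- function(counts, intensities = NULL, path) {
  rna <- data.frame(sample_id = counts$samples$sample_id,
                    genotype = counts$samples$genotype,
                    timepoint = counts$samples$timepoint,
                    layer = "rna", channel = "", stringsAsFactors = FALSE)
  sheet <- rna
  if (!is.null(intensities)) {
    prot <- data.frame(sample_id = intensities$channels$channel_id,
                       genotype = intensities$channels$genotype,
                       timepoint = intensities$channels$timepoint,
                       layer = "protein",
                       channel = intensities$channels$tmt_set,
                       stringsAsFactors = FALSE)
    sheet <- rbind(rna, prot)
  }
  write_tsv(sheet, path)
}

#' @rdname sample_sheet_io
#' @export
read_sample_sheet <- function(path) {
  read_tsv_strict(path, c("sample_id", "genotype", "timepoint", "layer"))
}

#' Write / read a differential table
#'
#' Shared schema across layers: `feature`, `layer`, `timepoint`,
#' `log2fc`, `p_raw`, `p_adj`, `mean_fpkm`, `detected`.
#'
#' @param tab Differential table data frame.
#' @param path File path.
#' @name differential_io
NULL

#' @rdname differential_io
#' @export
write_differential <- function(tab, path) {
  write_tsv(tab[, c("feature", "layer", "timepoint", "log2fc", "p_raw",
                    "p_adj", "mean_fpkm", "detected")], path)
}

#' @rdname differential_io
#' @export
read_differential <- function(path) {
  df <- read_tsv_strict(path, c("feature", "layer", "timepoint", "log2fc",
                                "p_raw", "p_adj"))
  if (!"detected" %in% names(df)) df$detected <- TRUE
  df$detected <- as.logical(df$detected)
  df
}

#' Principal-component QC of a feature matrix
#'
#' Singular value decomposition of the feature-centered matrix. For
#' determinism each component's sign is fixed so its largest-magnitude
#' feature loading is positive. A constant matrix yields all-zero
#' coordinates with a warning.
#'
#' @param x Numeric matrix, features x samples (e.g.
#'   `log2(normalized count + 1)` or log2 relative ratios).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components),
#'   `var_explained` (fraction per component), `loadings`
#'   (features x components).
#' @export
pca_qc <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("pca_qc: need >= 2 samples")
  n_components <- min(as.integer(n_components), ncol(x) - 1L, nrow(x))
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-12)) {
    warning("pca_qc: constant matrix; zero variance")
    return(list(scores = matrix(0, ncol(x), n_components,
                                dimnames = list(colnames(x), NULL)),
                var_explained = rep(0, n_components),
                loadings = matrix(0, nrow(x), n_components)))
  }
  sv <- svd(xc, nu = n_components, nv = n_components)
  for (j in seq_len(n_components)) {
    i_max <- which.max(abs(sv$u[, j]))
    if (sv$u[i_max, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  scores <- sweep(sv$v, 2, sv$d[seq_len(n_components)], "*")
  rownames(scores) <- colnames(x)
  list(scores = scores,
       var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
       loadings = sv$u)
}
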