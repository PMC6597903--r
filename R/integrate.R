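#' Correct isobaric-labelling ratio compression
#'
#' Reporter-ion co-isolation attenuates observed TMT fold changes; the
#' conventional remedy multiplies the observed protein log2 fold change
#' by a fixed factor (1.4 by default). The correction is exactly linear
#' and sign-preserving.
#'
#' @param log2fc Observed protein-layer log2 fold change(s).
#' @param factor Positive correction factor.
#' @return `factor * log2fc`.
#' @export
#' @examples
#' compression_correct(1.0)    # 1.4
#' compression_correct(-0.5)   # -0.7
compression_correct <- function(log2fc, factor = 1.4) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("compression_correct: factor must be a positive number")
  factor * log2fc
}

# Lookup helper: per-symbol significance flag and values for one table.
.cascade_layer <- function(tab, alpha) {
  if (is.null(tab) || nrow(tab) == 0)
    return(list(sym = character(), sig = logical(),
                log2fc = numeric(), p_adj = numeric()))
  sym <- toupper(tab$feature)
  if (anyDuplicated(sym))
    stop("cascade_merge: duplicate gene symbols within a table: ",
         paste(utils::head(unique(sym[duplicated(sym)]), 3), collapse = ", "))
  detected <- if ("detected" %in% names(tab)) tab$detected else TRUE
  sig <- !is.na(tab$p_adj) & tab$p_adj < alpha & detected
  list(sym = sym, sig = sig, log2fc = tab$log2fc, p_adj = tab$p_adj)
}

#' Significance-priority merge of the four differential tables
#'
#' Combines the protein and RNA differential tables from both timepoints
#' into one record per gene symbol. Per symbol the source is the first
#' significant table in the strict priority order protein/35 >
#' protein/56 > rna/35 > rna/56, where "significant" means FDR-adjusted
#' p below `alpha` (and, for RNA tables, robustly detected). A
#' protein-sourced log2 fold change is passed through
#' [compression_correct()]. A symbol missing from a table counts as
#' non-significant there. Symbols significant nowhere are handled per
#' `fallback`: `"carry_gene35"` (default) keeps the record with
#' `significant_any = FALSE`, carrying the values of the rna/35 table
#' (or, if the symbol is absent there, of the first table that contains
#' it in priority order) so the symbol remains in the enrichment
#' universe; `"exclude"` drops it.
#'
#' @param prot35,prot56,rna35,rna56 Differential tables (data frames
#'   with columns `feature`, `log2fc`, `p_adj`, and for RNA `detected`),
#'   as produced by [protein_differential()] and [nb_differential()].
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @param fallback `"carry_gene35"` or `"exclude"`.
#' @param factor Compression-correction factor applied to protein-sourced
#'   log2 fold changes.
#' @return Integrated table with one row per gene symbol: `gene_symbol`,
#'   `source_layer`, `source_timepoint`, `log2fc_integrated`,
#'   `p_adj_integrated`, `significant_any`, `direction`.
#' @export
cascade_merge <- function(prot35, prot56, rna35, rna56, alpha = 0.05,
                          fallback = c("carry_gene35", "exclude"),
                          factor = 1.4) {
  fallback <- match.arg(fallback)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("cascade_merge: alpha must lie in (0, 1)")
  layers <- list(
    list(tab = .cascade_layer(prot35, alpha), layer = "protein", tp = 35L),
    list(tab = .cascade_layer(prot56, alpha), layer = "protein", tp = 56L),
    list(tab = .cascade_layer(rna35, alpha), layer = "rna", tp = 35L),
    list(tab = .cascade_layer(rna56, alpha), layer = "rna", tp = 56L))

  symbols <- sort(unique(unlist(lapply(layers, function(l) l$tab$sym))))
  if (length(symbols) == 0) stop("cascade_merge: no symbols in any table")
  n <- length(symbols)

  src_layer <- rep(NA_character_, n)
  src_tp <- rep(NA_integer_, n)
  lfc <- rep(NA_real_, n)
  padj <- rep(NA_real_, n)
  sig_any <- rep(FALSE, n)

  take <- function(l, rows, idx) {
    j <- match(symbols[idx], l$tab$sym)
    v <- l$tab$log2fc[j]
    if (l$layer == "protein") v <- compression_correct(v, factor)
    src_layer[idx] <<- l$layer
    src_tp[idx] <<- l$tp
    lfc[idx] <<- v
    padj[idx] <<- l$tab$p_adj[j]
  }
  unassigned <- rep(TRUE, n)
  for (l in layers) {
    hit <- unassigned & symbols %in% l$tab$sym[l$tab$sig]
    if (any(hit)) {
      take(l, NULL, which(hit))
      sig_any[hit] <- TRUE
      unassigned[hit] <- FALSE
    }
  }
  if (any(unassigned) && fallback == "carry_gene35") {
    # carry rna/35 when present, else the first table holding the symbol
    for (l in layers[c(3, 1, 2, 4)]) {
      hit <- unassigned & symbols %in% l$tab$sym
      if (any(hit)) {
        take(l, NULL, which(hit))
        unassigned[hit] <- FALSE
      }
    }
  }
  out <- data.frame(gene_symbol = symbols, source_layer = src_layer,
                    source_timepoint = src_tp, log2fc_integrated = lfc,
                    p_adj_integrated = padj, significant_any = sig_any,
                    direction = ifelse(is.na(lfc), NA_character_,
                                       ifelse(lfc < 0, "down", "up")),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (fallback == "exclude") out <- out[out$significant_any, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag the enrichment input signature
#'
#' Membership in the differential signature used as enrichment input:
#' adjusted p below `p_max` and absolute linear fold change above
#' `fc_min` (i.e. `|log2fc| > log2(fc_min)`), in either direction.
#'
#' @param integrated Integrated table from [cascade_merge()].
#' @param p_max Significance threshold (default 0.05).
#' @param fc_min Linear fold-change threshold (default 1.5).
#' @return The table with an added logical `in_signature` column.
#' @export
signature_filter <- function(integrated, p_max = 0.05, fc_min = 1.5) {
  stopifnot(is.data.frame(integrated))
  if (!is.numeric(fc_min) || fc_min < 1)
    stop("signature_filter: fc_min must be >= 1")
  integrated$in_signature <-
    !is.na(integrated$p_adj_integrated) &
    integrated$p_adj_integrated < p_max &
    abs(integrated$log2fc_integrated) > log2(fc_min)
  integrated
}

#' Integrate the four differential tables and flag the signature
#'
#' Convenience wrapper running [cascade_merge()] then
#' [signature_filter()].
#'
#' @inheritParams cascade_merge
#' @inheritParams signature_filter
#' @return Integrated table with `in_signature` column.
#' @export
integrate_tables <- function(prot35, prot56, rna35, rna56, alpha = 0.05,
                             fallback = "carry_gene35", factor = 1.4,
                             p_max = 0.05, fc_min = 1.5) {
  signature_filter(
    cascade_merge(prot35, prot56, rna35, rna56, alpha = alpha,
                  fallback = fallback, factor = factor),
    p_max = p_max, fc_min = fc_min)
}
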