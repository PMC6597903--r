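#' Over-representation (hypergeometric) test
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k` or
#' more signature genes in the set, with `N` universe genes, `K` set
#' members in the universe and `n` signature genes.
#'
#' @param set Character vector of set member symbols.
#' @param signature Character vector of signature symbols (subset of the
#'   universe).
#' @param universe Character vector of all background symbols.
#' @return p-value.
#' @export
#' @examples
#' ora_test(paste0("g", 1:5), paste0("g", c(1:3, 10)), paste0("g", 1:20))
ora_test <- function(set, signature, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("ora_test: empty universe")
  signature <- intersect(unique(signature), universe)
  set <- intersect(unique(set), universe)
  N <- length(universe); K <- length(set); n <- length(signature)
  k <- length(intersect(set, signature))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Competitive rank-sum enrichment test
#'
#' Two-sided Wilcoxon rank-sum test comparing the gene-level scores of
#' in-set genes against all other universe genes, using the normal
#' approximation with tie and continuity corrections. If every score is
#' tied the test is uninformative and returns 1 with a warning.
#'
#' @param set Character vector of member symbols.
#' @param gene_stats Named numeric vector of per-universe-gene scores
#'   (e.g. `-log10` adjusted p).
#' @return p-value.
#' @export
rank_test <- function(set, gene_stats) {
  inset <- names(gene_stats) %in% set
  if (!any(inset) || all(inset))
    stop("rank_test: need >= 1 gene inside and outside the set")
  x <- gene_stats[inset]; y <- gene_stats[!inset]
  if (length(unique(gene_stats)) == 1L) {
    warning("rank_test: all scores tied; p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)$p.value)
}

#' Self-contained permutation enrichment test
#'
#' Observed statistic: mean score of the set's in-universe members. Null
#' distribution: the same mean recomputed on `n_perm` uniform random
#' gene subsets of the same size drawn from the universe. The p-value is
#' `(1 + #{T_perm >= T_obs}) / (n_perm + 1)`, bounded below by
#' `1/(n_perm + 1)`.
#'
#' @param set Character vector of member symbols.
#' @param gene_stats Named numeric vector of per-universe-gene scores.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutation stream.
#' @return p-value.
#' @export
perm_test <- function(set, gene_stats, n_perm = 9999L, seed = NULL) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop("perm_test: n_perm must be >= 99")
  inset <- which(names(gene_stats) %in% set)
  N <- length(gene_stats); m <- length(inset)
  if (m == 0L) stop("perm_test: no set member in the universe")
  if (m > N) stop("perm_test: set larger than universe")
  if (!is.null(seed)) set.seed(as.integer(seed))
  t_obs <- mean(gene_stats[inset])
  t_perm <- vapply(seq_len(n_perm),
                   function(i) mean(gene_stats[sample.int(N, m)]),
                   numeric(1))
  (1 + sum(t_perm >= t_obs)) / (n_perm + 1)
}

#' Combine ensemble p-values and ranks
#'
#' Fisher's method across the three base statistics per set
#' (`X = -2 * sum(log p)` against a chi-square with 6 df), plus the
#' median of the set's ranks under the three methods. Zero p-values are
#' clamped to 1e-300 before taking logs, with a warning.
#'
#' @param p_ora,p_rank,p_perm Numeric vectors of per-set p-values, one
#'   entry per set, aligned.
#' @return Data frame with `p_combined` and `median_rank` (sets ordered
#'   as given; ranking uses average ranks for ties).
#' @export
ensemble_combine <- function(p_ora, p_rank, p_perm) {
  pm <- cbind(p_ora, p_rank, p_perm)
  if (any(!is.finite(pm)) || any(pm < 0 | pm > 1))
    stop("ensemble_combine: p-values must lie in [0, 1]")
  if (any(pm == 0)) {
    warning("ensemble_combine: zero p-value clamped to 1e-300")
    pm[pm == 0] <- 1e-300
  }
  x <- -2 * rowSums(log(pm))
  p_combined <- stats::pchisq(x, df = 6, lower.tail = FALSE)
  ranks <- apply(pm, 2, rank)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  data.frame(p_combined = p_combined,
             median_rank = apply(ranks, 1, stats::median))
}

#' Ensemble gene-set enrichment on the integrated signature
#'
#' For every gene set: the over-representation test of the signature
#' against the universe, the competitive rank-sum test and the
#' self-contained permutation test on the gene-level score
#' `-log10(adjusted p)`, combined by Fisher's method;
#' Benjamini--Hochberg adjustment of the combined p across sets; a
#' signed direction score (mean integrated log2 fold change of the
#' set's members) labelling the set up- or down-regulated. Sets are
#' returned ordered by median rank, ties broken by combined p. A set is
#' `reported` when its adjusted combined p is below 0.05. The universe
#' is every symbol in the integrated table.
#'
#' @param integrated Integrated table with `in_signature` flags (see
#'   [integrate_tables()]).
#' @param collection A [geneset_collection()] with >= 2 sets.
#' @param n_perm Permutations for the self-contained member.
#' @param seed Integer seed for the permutation stream.
#' @return Data frame with one row per set: `set_name`,
#'   `n_members_in_universe`, `n_members_in_signature`, `p_ora`,
#'   `p_rank`, `p_perm`, `p_combined`, `p_adj`, `median_rank`,
#'   `direction_score`, `direction`, `reported`.
#' @export
enrich_all <- function(integrated, collection, n_perm = 9999L, seed = 1L) {
  stopifnot(is.data.frame(integrated), inherits(collection, "geneset_collection"))
  if (!"in_signature" %in% names(integrated))
    stop("enrich_all: integrated table lacks in_signature (run signature_filter)")
  if (length(collection$sets) < 2L) stop("enrich_all: need >= 2 sets")
  universe <- toupper(integrated$gene_symbol)
  signature <- universe[integrated$in_signature]
  if (length(signature) == 0)
    warning("enrich_all: empty signature; over-representation p-values are 1")
  gene_stats <- stats::setNames(
    -log10(pmax(integrated$p_adj_integrated, 1e-300)), universe)
  gene_stats[!is.finite(gene_stats)] <- 0
  lfc <- stats::setNames(integrated$log2fc_integrated, universe)

  set_names <- names(collection$sets)
  # Per-set permutation seed derived from the run seed and a stable hash
  # of the set name, so results do not depend on set order.
  set_seed_of <- function(nm) {
    h <- sum(utf8ToInt(nm) * seq_along(utf8ToInt(nm))) %% 1000003L
    (as.integer(seed) %% 100003L) * 1009L + h
  }
  res <- lapply(set_names, function(nm) {
    members <- intersect(toupper(collection$sets[[nm]]), universe)
    n_u <- length(members)
    n_s <- length(intersect(members, signature))
    if (n_u == 0L || n_u == length(universe)) {
      return(data.frame(set_name = nm, n_members_in_universe = n_u,
                        n_members_in_signature = n_s, p_ora = 1,
                        p_rank = 1, p_perm = 1, direction_score = 0))
    }
    data.frame(
      set_name = nm, n_members_in_universe = n_u,
      n_members_in_signature = n_s,
      p_ora = ora_test(members, signature, universe),
      p_rank = rank_test(members, gene_stats),
      p_perm = perm_test(members, gene_stats, n_perm = n_perm,
                         seed = set_seed_of(nm)),
      direction_score = mean(lfc[members]))
  })
  out <- do.call(rbind, res)
  comb <- ensemble_combine(out$p_ora, out$p_rank, out$p_perm)
  out$p_combined <- comb$p_combined
  out$median_rank <- comb$median_rank
  out$p_adj <- bh_adjust(out$p_combined)
  out$direction <- ifelse(out$direction_score < 0, "down", "up")
  out$reported <- out$p_adj < 0.05
  out <- out[order(out$median_rank, out$p_combined), ]
  rownames(out) <- NULL
  out[, c("set_name", "n_members_in_universe", "n_members_in_signature",
          "p_ora", "p_rank", "p_perm", "p_combined", "p_adj",
          "median_rank", "direction_score", "direction", "reported")]
}
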