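#' Median-of-ratios size factors
#'
#' Per-sample scaling factors estimated as the median, over genes with a
#' positive geometric mean across samples, of the ratio of the gene's
#' count to its geometric-mean pseudo-reference. This is the standard
#' normalization of the negative-binomial differential-expression family.
#'
#' @param x A [count_matrix()] or a bare counts matrix.
#' @return Named positive numeric vector, one size factor per sample.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' rownames(m) <- paste0("g", 1:3)
#' size_factors(m)  # (1/sqrt(2), sqrt(2))
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  logs <- log(counts)
  loggeo <- rowMeans(logs)
  use <- is.finite(loggeo)
  if (!any(use))
    stop("size factor estimation error: no gene has nonzero counts in all samples")
  sf <- apply(logs[use, , drop = FALSE], 2,
              function(lc) exp(stats::median(lc - loggeo[use])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factor estimation error: non-positive size factor")
  sf
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM_ij = counts_ij * 1e9 / (length_i * total_counts_j)`, using the
#' annotated gene length (no effective-length correction).
#'
#' @param x A [count_matrix()], or a counts matrix if `lengths_bp` given.
#' @param lengths_bp Per-gene lengths in bp (ignored for `count_matrix`).
#' @return Numeric matrix of FPKM values, genes x samples.
#' @export
fpkm <- function(x, lengths_bp = NULL) {
  if (inherits(x, "count_matrix")) {
    counts <- x$counts
    lengths_bp <- x$lengths_bp
  } else {
    counts <- as.matrix(x)
    if (is.null(lengths_bp))
      stop("fpkm: lengths_bp required for a bare matrix")
  }
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("fpkm: zero library total")
  sweep(counts * 1e9 / lengths_bp, 2, totals, "/")
}

#' Robust-detection filter on mean FPKM
#'
#' A feature is robustly detected when its mean FPKM strictly exceeds
#' `fpkm_min` (default 0.5). Undetected features remain in downstream
#' tables but are excluded from the multiple-testing universe and the
#' differential signature.
#'
#' @param mean_fpkm Numeric vector of per-feature mean FPKM.
#' @param fpkm_min Detection threshold (strict `>`).
#' @return Logical vector.
#' @export
detection_filter <- function(mean_fpkm, fpkm_min = 0.5) {
  mean_fpkm > fpkm_min
}

# Per-gene method-of-moments NB dispersion from normalized counts:
# pooled excess of within-group variance over the group mean, scaled by
# the squared group means.
moment_dispersion <- function(nc, is_mut) {
  g <- list(!is_mut, is_mut)
  num <- 0; den <- 0
  for (idx in g) {
    n <- sum(idx)
    mu <- rowMeans(nc[, idx, drop = FALSE])
    v <- apply(nc[, idx, drop = FALSE], 1, stats::var)
    num <- num + (n - 1) * (v - mu)
    den <- den + (n - 1) * mu^2
  }
  pmax(ifelse(den > 0, num / den, 0), 1e-8)
}

# Parametric mean-dispersion trend alpha(mu) = a0 + a1/mu fitted by a
# Gamma-family GLM to the per-gene moment estimates, iterating once to
# drop gross outliers; falls back to the median when the fit degenerates.
fit_dispersion_trend <- function(mu, disp) {
  const_fit <- function() {
    a <- max(stats::median(disp, na.rm = TRUE), 1e-8)
    function(m) rep(a, length(m))
  }
  ok <- is.finite(disp) & disp > 1e-7 & is.finite(mu) & mu > 1
  if (sum(ok) < 50) return(const_fit())
  d <- disp[ok]; m <- mu[ok]
  coefs <- NULL
  for (iter in 1:2) {
    fit <- tryCatch(
      stats::glm(d ~ I(1 / m), family = stats::Gamma(link = "identity"),
                 start = c(stats::median(d), 1)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) return(const_fit())
    coefs <- pmax(stats::coef(fit), 0)
    pred <- coefs[1] + coefs[2] / m
    keep <- d / pmax(pred, 1e-8) < 15 & d / pmax(pred, 1e-8) > 1e-4
    if (all(keep)) break
    d <- d[keep]; m <- m[keep]
    if (length(d) < 50) return(const_fit())
  }
  if (is.null(coefs) || !all(is.finite(coefs))) return(const_fit())
  function(mm) pmax(coefs[1] + coefs[2] / pmax(mm, 1e-8), 1e-8)
}

#' Two-group negative-binomial Wald differential expression
#'
#' Differential expression between mutant and control at one timepoint.
#' Counts are normalized by [size_factors()]; per gene the log2 fold
#' change is `log2((mu_mut + eps) / (mu_ctl + eps))` with pseudocount
#' `eps = 0.5 / median(size factors)`; the NB dispersion is estimated by
#' method of moments per gene and, by default, smoothed by a fitted
#' mean--dispersion trend shared across genes; the Wald statistic uses the
#' delta-method standard error of the log2 ratio under the NB
#' mean-variance relation, with a two-sided normal p-value.
#' Benjamini--Hochberg adjustment is applied over robustly detected genes
#' only; undetected genes keep `p_adj = NA`.
#'
#' @param x A [count_matrix()] containing both genotypes at `timepoint`.
#' @param timepoint 35 or 56.
#' @param fpkm_min Detection threshold on mean FPKM across the
#'   timepoint's samples (strict `>`).
#' @param dispersion `"trend"` (default) uses the fitted mean--dispersion
#'   trend in the Wald SE; `"gene"` uses the raw per-gene moment
#'   estimate.
#' @return A differential table (data frame) with columns `feature`,
#'   `layer`, `timepoint`, `log2fc`, `p_raw`, `p_adj`, `mean_fpkm`,
#'   `detected`.
#' @export
nb_differential <- function(x, timepoint, fpkm_min = 0.5,
                            dispersion = c("trend", "gene")) {
  stopifnot(inherits(x, "count_matrix"))
  dispersion <- match.arg(dispersion)
  timepoint <- as.integer(timepoint)
  sel <- x$samples$timepoint == timepoint
  if (!any(sel)) stop("nb_differential: no samples at timepoint ", timepoint)
  counts <- x$counts[, sel, drop = FALSE]
  samples <- x$samples[sel, ]
  is_mut <- samples$genotype == "mutant"
  if (sum(is_mut) < 2L || sum(!is_mut) < 2L)
    stop("nb_differential: need >= 2 samples per genotype at timepoint ",
         timepoint)
  for (gname in c("control", "mutant")) {
    gi <- samples$genotype == gname
    if (all(counts[, gi, drop = FALSE] == 0))
      stop("nb_differential: all counts zero in group '", gname, "'")
  }

  sf <- size_factors(counts)
  nc <- sweep(counts, 2, sf, "/")
  n_c <- sum(!is_mut); n_m <- sum(is_mut)
  mu_c <- rowMeans(nc[, !is_mut, drop = FALSE])
  mu_m <- rowMeans(nc[, is_mut, drop = FALSE])
  mu_bar <- (n_c * mu_c + n_m * mu_m) / (n_c + n_m)

  disp_gene <- moment_dispersion(nc, is_mut)
  disp <- if (dispersion == "trend") {
    fit_dispersion_trend(mu_bar, disp_gene)(mu_bar)
  } else disp_gene

  eps <- 0.5 / stats::median(sf)
  log2fc <- log2((mu_m + eps) / (mu_c + eps))

  # Var(mean of normalized counts) under Var(k/s) = mu/s + alpha*mu^2,
  # then delta method for the log2 of the (pseudocounted) group mean.
  inv_c <- sum(1 / sf[!is_mut]); inv_m <- sum(1 / sf[is_mut])
  var_mu_c <- (mu_c * inv_c / n_c^2) + disp * mu_c^2 / n_c
  var_mu_m <- (mu_m * inv_m / n_m^2) + disp * mu_m^2 / n_m
  se2 <- (var_mu_c / (mu_c + eps)^2 + var_mu_m / (mu_m + eps)^2) / log(2)^2
  z <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  p_raw <- 2 * stats::pnorm(-abs(z))

  mean_fpkm <- rowMeans(fpkm(counts, x$lengths_bp[rownames(counts)]))
  detected <- detection_filter(mean_fpkm, fpkm_min)
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[detected] <- bh_adjust(p_raw[detected])

  data.frame(feature = rownames(counts), layer = "rna",
             timepoint = timepoint, log2fc = log2fc, p_raw = p_raw,
             p_adj = p_adj, mean_fpkm = mean_fpkm, detected = detected,
             row.names = NULL, stringsAsFactors = FALSE)
}
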