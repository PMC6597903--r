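#' Channel-median normalization of TMT intensities
#'
#' Each channel is divided by its own median intensity over proteins,
#' then rescaled by the mean of the original channel medians so the
#' global intensity scale is preserved. After normalization all channel
#' medians are equal. Zeros and non-finite values are treated as missing
#' and ignored when computing medians.
#'
#' @param x An [intensity_matrix()] or a bare positive matrix.
#' @return Same type as the input, normalized.
#' @export
channel_median_normalize <- function(x) {
  m <- if (inherits(x, "intensity_matrix")) x$intensities else as.matrix(x)
  m[!is.finite(m) | m <= 0] <- NA_real_
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  bad <- !is.finite(med)
  if (any(bad))
    stop("channel_median_normalize: no finite intensities in channel(s) ",
         paste(colnames(m)[bad], collapse = ", "))
  out <- sweep(m, 2, med, "/") * mean(med)
  if (inherits(x, "intensity_matrix")) {
    x$intensities <- out
    x
  } else out
}

#' Relative-ratio transformation
#'
#' Each protein's normalized intensities are divided by the protein's own
#' mean across the channels of the TMT set, so every row has mean exactly
#' 1. Missing values are ignored in the row mean.
#'
#' @param x An [intensity_matrix()] or bare matrix of normalized
#'   intensities.
#' @return Same type as the input, rows scaled to mean 1.
#' @export
relative_ratio <- function(x) {
  m <- if (inherits(x, "intensity_matrix")) x$intensities else as.matrix(x)
  m[!is.finite(m) | m <= 0] <- NA_real_
  rm <- rowMeans(m, na.rm = TRUE)
  out <- m / rm
  if (inherits(x, "intensity_matrix")) {
    x$intensities <- out
    x
  } else out
}

# Solve trigamma(d0/2) = v for d0 by bisection on (0.1, 500]; trigamma is
# strictly decreasing, so clamp outside the bracket.
solve_prior_df <- function(v) {
  lo <- 0.1; hi <- 500
  if (v >= trigamma(lo / 2)) return(lo)
  if (v <= trigamma(hi / 2)) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) > v) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per protein, an ordinary two-group fit on log2 relative ratios gives
#' the log2 fold change (difference of group means) and the pooled
#' residual variance `s2` on `df = n_c + n_m - 2` degrees of freedom.
#' The per-protein variances are then shrunk towards a prior: assuming
#' `s2 ~ s2_0 * F(df, d0)`, the prior degrees of freedom `d0` and prior
#' variance `s2_0` are estimated by matching the first two moments of
#' `log(s2)` (the excess of the empirical variance of `log s2` over its
#' expected sampling variance `trigamma(df/2)` determines `d0` through a
#' bisection solve of the trigamma equation; `d0 = Inf` when there is no
#' excess). The posterior variance
#' `s2_post = (d0*s2_0 + df*s2) / (d0 + df)` yields the moderated
#' statistic `t = log2fc / sqrt(s2_post * (1/n_c + 1/n_m))` with
#' `df + d0` degrees of freedom.
#'
#' Proteins quantified in fewer than 2 channels per group are excluded
#' with a warning. Missing values reduce the residual degrees of freedom
#' of the affected protein.
#'
#' @param ratios Matrix of relative ratios (proteins x channels); the
#'   test operates on `log2(ratios)`.
#' @param groups Character/factor of `"control"`/`"mutant"` per channel.
#' @param d0 Optional forced prior degrees of freedom (`0` recovers the
#'   ordinary pooled t-test exactly; `Inf` fully trusts the prior).
#' @param s2_0 Optional forced prior variance (requires `d0`).
#' @return Data frame with columns `feature`, `log2fc`, `s2`, `df`,
#'   `s2_0`, `d0`, `s2_post`, `t_mod`, `p_raw`, `p_adj`.
#' @export
moderated_t <- function(ratios, groups, d0 = NULL, s2_0 = NULL) {
  m <- log2(as.matrix(ratios))
  m[!is.finite(m)] <- NA_real_
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    stop("moderated_t: one group label per column required")
  if (!all(groups %in% c("control", "mutant")))
    stop("moderated_t: groups must be 'control' or 'mutant'")
  ic <- groups == "control"; im <- groups == "mutant"

  n_c <- rowSums(!is.na(m[, ic, drop = FALSE]))
  n_m <- rowSums(!is.na(m[, im, drop = FALSE]))
  keep <- n_c >= 2L & n_m >= 2L
  if (!all(keep))
    warning("moderated_t: excluding ", sum(!keep),
            " protein(s) quantified in < 2 channels per group")
  if (!any(keep)) stop("moderated_t: no protein quantified in both groups")
  m <- m[keep, , drop = FALSE]
  n_c <- n_c[keep]; n_m <- n_m[keep]

  mu_c <- rowMeans(m[, ic, drop = FALSE], na.rm = TRUE)
  mu_m <- rowMeans(m[, im, drop = FALSE], na.rm = TRUE)
  log2fc <- mu_m - mu_c
  ss_c <- rowSums((m[, ic, drop = FALSE] - mu_c)^2, na.rm = TRUE)
  ss_m <- rowSums((m[, im, drop = FALSE] - mu_m)^2, na.rm = TRUE)
  df <- n_c + n_m - 2
  s2 <- (ss_c + ss_m) / df

  if (is.null(d0)) {
    # Moment matching of log(s2): e_i has mean log(s2_0) + c(d0) and
    # variance trigamma(df_i/2) + trigamma(d0/2).
    z <- log(pmax(s2, 1e-300))
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (!is.finite(evar) || evar <= 0) {
      d0 <- Inf
      s2_0 <- exp(mean(e))
    } else {
      d0 <- solve_prior_df(evar)
      s2_0 <- exp(mean(e) - log(d0 / 2) + digamma(d0 / 2))
    }
  } else {
    if (d0 < 0) stop("moderated_t: d0 must be >= 0")
    if (is.null(s2_0)) s2_0 <- if (d0 == 0) 0 else stats::median(s2)
  }

  s2_post <- if (is.infinite(d0)) rep(s2_0, length(s2)) else
    (d0 * s2_0 + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n_c + 1 / n_m))
  t_mod <- ifelse(se > 0, log2fc / se, 0)
  df_total <- df + d0
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_raw[se == 0 & log2fc == 0] <- 1

  data.frame(feature = rownames(m), log2fc = log2fc, s2 = s2, df = df,
             s2_0 = s2_0, d0 = d0, s2_post = s2_post, t_mod = t_mod,
             p_raw = p_raw, p_adj = bh_adjust(p_raw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' `adj_(i) = min_(j >= i) min(1, p_(j) * m / j)`, returned in the input
#' order.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("bh_adjust: p must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Protein-layer differential abundance for one timepoint
#'
#' Runs the full TMT workflow on one 10-plex set: channel-median
#' normalization, relative-ratio transformation, and the moderated
#' t-test on log2 ratios, then collapses proteins to gene symbols
#' (keeping, per symbol, the protein with the highest mean raw
#' intensity) to produce a differential table aligned with the RNA
#' layer's schema.
#'
#' @param x An [intensity_matrix()].
#' @param timepoint 35 or 56.
#' @param ... Passed to [moderated_t()].
#' @return Differential table with columns `feature` (gene symbol),
#'   `layer = "protein"`, `timepoint`, `log2fc`, `p_raw`, `p_adj`,
#'   `mean_fpkm` (`NA`), `detected` (`TRUE`).
#' @export
protein_differential <- function(x, timepoint, ...) {
  stopifnot(inherits(x, "intensity_matrix"))
  timepoint <- as.integer(timepoint)
  sel <- x$channels$timepoint == timepoint
  if (!any(sel)) stop("protein_differential: no channels at timepoint ",
                      timepoint)
  raw <- x$intensities[, sel, drop = FALSE]
  raw[!is.finite(raw) | raw <= 0] <- NA_real_
  groups <- x$channels$genotype[sel]

  ratios <- relative_ratio(channel_median_normalize(raw))
  fit <- moderated_t(ratios, groups, ...)

  # Collapse to one protein per gene symbol: highest mean raw intensity.
  sym <- toupper(x$gene_symbols[match(fit$feature, x$protein_ids)])
  mean_int <- rowMeans(raw, na.rm = TRUE)[fit$feature]
  ord <- order(sym, -mean_int)
  fit <- fit[ord, ]; sym <- sym[ord]
  keep <- !duplicated(sym)
  fit <- fit[keep, ]; sym <- sym[keep]

  data.frame(feature = sym, layer = "protein", timepoint = timepoint,
             log2fc = fit$log2fc, p_raw = fit$p_raw,
             p_adj = bh_adjust(fit$p_raw), mean_fpkm = NA_real_,
             detected = TRUE, row.names = NULL, stringsAsFactors = FALSE)
}
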