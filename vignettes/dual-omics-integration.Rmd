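---
title: "Integrating RNA-seq and TMT proteomics from a two-genotype neuronal time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating RNA-seq and TMT proteomics from a two-genotype neuronal time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualomics)
```

# The analysis problem

`dualomics` implements a complete differential workflow for studies that
assay the same two-genotype contrast (control vs mutant, e.g. an
iPSC-derived neuronal line carrying a pathogenic kinase mutation against
isogenic or donor controls) at two culture ages (35 and 56 days in
vitro, DIV) on two molecular layers: bulk RNA-seq counts and TMT-10plex
protein reporter intensities. The four resulting differential tables —
protein/35, protein/56, RNA/35, RNA/56 — are merged into a single
gene-level signature by a significance-priority cascade and interrogated
by an ensemble gene-set enrichment. Because real data of this design are
rarely deposited, the package ships a seeded generator that plants known
effects, so every stage is verifiable against ground truth.

# Layer models

## RNA: negative-binomial Wald test

Counts $k_{ij}$ for gene $i$ in sample $j$ are modelled as negative
binomial with mean $\mu_i s_j$ and variance $\mu + \alpha\mu^2$, where
the size factors $s_j$ are the classical median-of-ratios estimator
(`size_factors()`): the median over genes, restricted to genes with a
positive geometric mean across samples, of $k_{ij}$ divided by the
gene's geometric-mean pseudo-reference. Per gene and timepoint the two
genotype means of the normalized counts are compared on the log2 scale:

$$\widehat{\mathrm{lfc}}_i = \log_2\frac{\hat\mu_{i,\mathrm{mut}}+\varepsilon}{\hat\mu_{i,\mathrm{ctl}}+\varepsilon},
\qquad \varepsilon = \frac{0.5}{\mathrm{median}(s)}$$

with a delta-method standard error derived from the NB mean–variance
relation and a two-sided normal p-value (`nb_differential()`). The
pseudocount bounds fold changes of empty groups without changing
well-expressed genes materially.

**Dispersion.** The raw per-gene moment estimator
$\hat\alpha_i = \sum_g (n_g-1)(v_g-\hat\mu_g) \,/\, \sum_g (n_g-1)\hat\mu_g^2$
has only $\sim$8 degrees of freedom at $n=5$ per group; plugging it into
a Wald statistic treated as standard normal inflates the type-I error.
We therefore fit a parametric mean–dispersion trend
$\alpha(\mu)=a_0+a_1/\mu$ to the moment estimates by a Gamma-family GLM
(one outlier-trimming pass, with a median fallback when the fit
degenerates) and use the trend value in the standard error — the same
information-sharing idea the NB differential-expression family relies
on, kept in closed form. `dispersion = "gene"` retains the raw
estimates. With the trend, the fraction of null genes at $p<0.05$ sits
within [0.035, 0.065] in simulation, which is what the calibration
tests assert.

**Detection.** A gene is robustly detected when its mean FPKM across the
timepoint's samples strictly exceeds 0.5
($\mathrm{FPKM}_{ij}=k_{ij}\cdot 10^9/(L_i\,T_j)$ with annotated length
$L_i$, no effective-length correction, and library total $T_j$).
Benjamini–Hochberg adjustment runs over detected genes only; undetected
genes keep `p_adj = NA` and can never enter the signature. Detection
uses the mean across all samples of the timepoint, not within-genotype
means.

## Protein: TMT normalization and moderated t

Within one 10-plex set, each channel is divided by its median intensity
over proteins and rescaled by the mean of the original medians
(`channel_median_normalize()`; medians agree to within 1e-9 relative
afterwards), then each protein is divided by its own mean across the
set's channels (`relative_ratio()`, row means exactly 1). Analysis
proceeds on $\log_2$ relative ratios: variance-stabilized, and a
constant per-protein scale cancels.

`moderated_t()` shrinks the per-protein pooled variance $s^2_i$ (df
$d_i=n_c+n_m-2$, reduced by missing channels; proteins with fewer than
two quantified channels per group are excluded with a warning) towards
a prior through the scaled-F model $s^2 \sim s^2_0 F(d, d_0)$. The
hyperparameters come from matching the first two moments of $\log s^2$:
after removing the known per-protein offset
($e_i = \log s_i^2 - \psi(d_i/2) + \log(d_i/2)$), the excess of
$\mathrm{var}(e)$ over the expected sampling variance
$\overline{\psi'(d_i/2)}$ equals $\psi'(d_0/2)$, which we invert by
bisection on $d_0 \in (0.1, 500]$ (the trigamma function is monotone;
no excess $\Rightarrow d_0=\infty$, i.e. full shrinkage). Then

$$s^2_{\mathrm{post}} = \frac{d_0 s^2_0 + d\, s^2}{d_0 + d},\qquad
t = \frac{\widehat{\mathrm{lfc}}}{\sqrt{s^2_{\mathrm{post}}\,(1/n_c+1/n_m)}}
\;\sim\; t_{d+d_0}.$$

Forcing $d_0=0$ recovers the ordinary pooled t-test exactly, which is
the reduction the tests exploit as an oracle; with the hyperparameters
forced to those of an independent reference implementation the
statistics agree to machine precision. When several proteins map to one
gene symbol the one with the highest mean raw intensity represents the
gene, a deterministic rule chosen because the join into the cascade
must be one-to-one.

# Ratio compression and its correction

Isobaric labelling underestimates true fold changes because co-isolated
background peptides dilute reporter ratios. The generator models this
directly: observed protein log2 fold change = `compression_factor`
$\times$ true log2 fold change (default $1/1.4$). The analysis-side
correction multiplies protein-sourced log2 fold changes by 1.4
(`compression_correct()`), exactly linear and sign-preserving. The
factor is applied on the log2 fold-change scale: a constant multiplier
on raw intensities would cancel in relative ratios and correct nothing,
so the ratio scale is the only reading under which the correction has
an effect. Both the factor and its application point are configurable.

# The significance-priority cascade

Per gene symbol (upper-cased for the cross-layer join), the integrated
record takes the first significant source in the strict order
protein/35 > protein/56 > RNA/35 > RNA/56, where significant means
FDR-adjusted p < `alpha` (0.05) — and, for RNA entries, robustly
detected. The fold-change gate is *not* part of cascade significance;
it belongs only to the enrichment input filter, mirroring how the two
thresholds are used downstream (both are configurable). Protein-sourced
fold changes pass through the compression correction. Genes significant
nowhere are, by default (`fallback = "carry_gene35"`), retained with
`significant_any = FALSE` carrying the RNA/35 values — enrichment needs
a defined universe — or, when a gene is absent from the RNA/35 table,
the first table in priority order that contains it; `fallback =
"exclude"` drops them. `signature_filter()` then flags the enrichment
input: adjusted p < 0.05 **and** |FC| > 1.5 in either direction
(|log2 FC| > log2 1.5).

# Ensemble enrichment

Named ensemble methods exist for gene-set testing; this package uses an
explicit, fully testable triple spanning the standard taxonomy:

* **Over-representation** (`ora_test()`): hypergeometric upper tail
  $P(X \ge k)$ of the signature/set overlap against the integrated
  universe.
* **Competitive rank-sum** (`rank_test()`): two-sided Wilcoxon
  rank-sum of in-set vs out-of-set gene scores
  ($-\log_{10}$ adjusted p), normal approximation with tie and
  continuity corrections.
* **Self-contained permutation** (`perm_test()`): mean in-set score
  against `n_perm` (default 9999) random same-size gene subsets, with
  the add-one p-value floor $1/(n_\mathrm{perm}+1)$. Each set's
  permutation stream is seeded from the run seed plus a stable hash of
  the set name, so results are independent of set order.

The three p-values are combined by Fisher's method
($-2\sum\ln p \sim \chi^2_6$; zero p clamped at 1e-300 with a warning),
sets are ordered by the median of their three per-method ranks (ties by
combined p), BH adjustment runs across sets, and a set is *reported*
when adjusted combined p < 0.05. The three members are positively
dependent, making the Fisher combination conservative-to-nominal rather
than exact, which is acceptable for a ranking instrument and is what
the null-simulation test checks. A signed direction score — the mean
integrated log2 fold change of the set's members — labels reported sets
up- or down-regulated; it is a qualitative annotation, not a fourth
test.

# What the generator emulates, and what it does not

`sim_config()` defaults describe the emulated study: ~16,000 genes with
~10,500 proteins (a deterministic prefix of the gene symbols, so joins
are reproducible), 5 samples per genotype per timepoint (one full
10-plex per timepoint), log-normal baseline expression, NB counts with
dispersion 0.05, log-normal library sizes (CV 0.15), gene lengths
log-uniform on [500, 20000] bp so the FPKM filter bites, protein
baselines N(20, 2) on log2 with channel offsets (sd 0.5) and residual
noise (sd 0.25), planted effects of |log2 FC| = 1 on 10% of genes
persisting across timepoints and layers, attenuated by $1/1.4$ in the
protein layer. Planted gene sets draw 60% of members from the
differential genes. Each layer draws from its own RNG stream derived
from the master seed by a fixed offset, so generating one layer never
perturbs another; a fixed configuration is byte-identical across runs.

Deliberately *not* modelled: peptide/spectrum-level structure,
missing-not-at-random dropout, batch structure beyond channel offsets,
inter-gene correlation within sets, and timepoint-specific effects.
Passing tests therefore demonstrate the pipeline's statistical
correctness under its own assumptions — calibration, recovery,
determinism — not robustness to the messier failure modes of real
acquisitions.

# Numerical choices and verification sizes

* Dispersion floor 1e-8; trend fallback to the median moment estimate.
* Pseudocount $\varepsilon = 0.5/\mathrm{median}(s)$ in the RNA fold
  change only (not in detection).
* Bisection for $d_0$ on (0.1, 500], 200 iterations or bracket width
  1e-10; values outside the bracket clamp to its ends.
* Permutation p floored at $1/(n_\mathrm{perm}+1)$; `n_perm` must be
  at least 99.
* All TSV output is UTF-8, tab-separated, header row, '.' decimal, no
  row names; GMT follows the tab-delimited name/description/members
  dialect with within-set member deduplication.
* The run manifest records thresholds, seeds and md5 checksums of every
  artifact; identical configuration implies identical checksums.

The verification suite works at deliberately scaled sizes chosen to
exercise every code path while keeping a full run in well under a
minute of simulation per scenario: 5,000 genes / 2,000 proteins for
null calibration (three seeds), 3,000 / 1,500 for effect recovery, and
twenty end-to-end runs at 2,000 genes / 1,000 proteins with one
planted 20-gene set among 50 decoys for pathway recovery. These sizes
are the package's own verification conditions; the generator's defaults
describe the full-scale study.

# Known limitations

* The RNA Wald test relies on asymptotic normality of the log group
  means; genes with very low counts are anti-conservative at extreme
  quantiles, which the detection filter largely removes from the
  inferential universe.
* The cascade selects rather than pools: a gene mildly but consistently
  perturbed in all four tables can lose to one strongly perturbed in a
  single table; meta-analytic combination is out of scope by design.
* The compression correction is a single global multiplier; real
  co-isolation interference varies per precursor.
* The ensemble's Fisher combination treats three dependent tests as
  independent and is therefore conservative under the null rather than
  exactly calibrated.
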