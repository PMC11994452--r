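---
title: "Methods: cell-type resolution of AF expression programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type resolution of AF expression programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`afcellsig` integrates bulk RNA-seq cohorts with a paired snRNA/snATAC
(multiome) dataset to place atrial-fibrillation expression changes into
cardiac cell types and to nominate driver transcription factors. This
vignette is the package's account of the statistical machinery, the
defaults, and the choices made where the design was genuinely open.

## Differential expression engine

Counts are modeled per gene as negative binomial with log link,

$$\log \mu_{sg} = x_s^\top \beta_g + \log f_s,$$

where $f_s$ are median-of-ratios size factors (geometric-mean
pseudo-reference over genes positive in every sample). The dispersion
$\alpha_g$ (variance $\mu + \alpha\mu^2$) is estimated by method of
moments on normalized counts *within each condition group and pooled*,
so a true condition effect does not inflate the estimate; values are
floored at $10^{-8}$, where the fit coincides with the Poisson GLM (an
invariant checked against the closed-form Poisson rate ratio). The
condition coefficient is tested with a Wald z statistic; p-values use the
normal reference and Benjamini–Hochberg correction across genes with
non-missing statistics. Reported fold changes are unshrunk maximum
likelihood estimates: no empirical-Bayes dispersion trend and no
LFC shrinkage are applied, because the downstream thresholds
(|log2FC| > 0.25 for the signature, > 0.05 for the network prefilter)
are calibrated here on the MLE scale, and simulation shows the Wald test
holds its nominal size (null rejection ≈ 0.05–0.06 at α = 0.2,
20 + 20 samples) while recovering a planted two-fold change with bias
below 0.1.

Cross-cohort *concordance* is read literally: a gene must reach
FDR < 0.05 separately in both cohorts with the same sign. The laxer
reading — significant in one cohort with a concordant sign in the other —
is available as `mode = "either"` in `concordant_degs()`.

The strandedness check exploits a planted overlapping antisense pair: in
the "unstranded" variant matrix both genes report their summed counts, so
the non-differential partner inherits its neighbour's signal and is
flagged when it is significant only without strand information.

## Specificity scoring and the CM AF signature

Cell-type specificity uses the one-vs-rest Wilcoxon rank-sum test with
midranks; AUC = U/(n₁n₂); the p-value uses the tie-corrected normal
approximation without continuity correction, and FDR is computed within
each cell-type contrast, never pooled. The test is two-sided — whether
the original screen used a one-sided p is not determinable from the
method description, and the AUC > 0.5 filter already encodes the
direction; the choice only affects the FDR filter and is symmetric for
the down-signature.

The signature intersects three evidence sets (CM AUC strictly > 0.5 at
FDR < 0.05; DE in cohort 1; DE in cohort 2, both at FDR < 0.05 and
|log2FC| strictly > 0.25), applied symmetrically to up- and
down-regulated genes. Relaxing any threshold can only grow the sets
(a tested monotonicity property).

Module scores use the binned-control construction: genes are placed into
24 equal-frequency bins by mean expression (quantile cuts avoid empty
bins on skewed means), each signature gene draws 100 controls with
replacement from its bin (excluding itself when possible), and the score
is mean(signature) − mean(controls) per observation. The bin count and
control count are the reference implementation's defaults; the seed is an
explicit argument so scores are reproducible.

## Meta-cells

Within each donor × cell-type group with ≥ k nuclei, nuclei are embedded
by PCA (10 components on centered, unit-variance log-normalized
expression), and a greedy randomized pass emits each visited nucleus's
k-nearest neighbourhood (k = 30, self included, Euclidean metric) as a
meta-cell iff it shares at most 10 nuclei with every meta-cell already
emitted in the group. The reference meta-cell tool does not document its
seed-selection order, so this package makes the simplest deterministic
choice: exhaust eligible seeds in seeded random order, no target count.
The overlap bound, size, donor/cell-type purity, and the monotone effect
of `max_shared` are asserted exhaustively in the tests. The identical
assignment is applied to the RNA and ATAC matrices.

## Motif activity and footprints

Motif deviations follow the chromVAR construction. For motif $m$ and
nucleus $i$: $X_{im}$ sums counts over member peaks,
$E_{im} = f_i \sum_{p \in m} w_p$ with $w_p$ the peak's share of the
grand total, and the raw deviation is $(X - E)/E$. Fifty background peak
sets, matched on GC content and log mean accessibility via a 10 × 10
equal-frequency quantile grid (a simpler, exhaustively testable stand-in
for nearest-neighbour bias matching), yield the bias correction and the
z-score denominator. Peak totals are summed as integers before any
division, so the motif containing every peak has deviation exactly zero.
Under a null simulation the per-motif z-scores have |mean| < 0.02 and
SD ≈ 0.95–1.1; z-scores are invariant to globally doubling counts.

Footprints count Tn5 insertions per base in ±250 bp around motif-site
midpoints (minus-strand sites are orientation-flipped), summed over sites
and group members and divided by the mean over the 200–250 bp flanks.
No Tn5 sequence-bias correction is applied — the synthetic insertions
carry no hexamer bias, and the flank normalization alone reproduces the
qualitative signature: zero in the protected core, elevated shoulders,
stronger in AF cardiomyocytes.

## Driver-TF selection

Signature scores of CM meta-cells are correlated (Pearson, two-sided t
p-value) with each TF's motif z-score and, separately, with each TF's
expression; FDR is computed within each arm across the TFs carrying
motifs. A TF is flagged when both arms reach FDR < 0.01; the sign is
retained, since a repressive driver anti-correlates in expression.
Outlier meta-cell exclusion is an explicit id list (clinical judgement,
not an algorithm). The final cell-type ranking multiplies the expression
AUC and the motif-activity AUC.

## Coexpression modules

Merged cohorts (cohort indicator and sex as covariates) are filtered to
genes with base mean > 1, |log2FC| > 0.05, p < 0.05, transformed as
log1p of normalized counts, and residualized against sex and cohort by
per-gene least squares on centered covariates (grand means preserved).
The signed adjacency is $((1+r)/2)^9$ and the topological overlap
follows the standard formula; both are validated against naive oracles
to 1e-12. Modules come from average-linkage clustering of 1 − TOM with a
*static* cut at 0.6 of the merge-height range: dynamic tree cutting is
deliberately not reimplemented, and the 0.6 fraction was chosen because,
on planted-block designs, block formation completes below ~0.85 of the
height range while noise genes attach above ~0.96, giving exact recovery
(ARI = 1) anywhere in 0.5–0.7 — a cut near the top of the range would
absorb the noise genes into modules. Clusters under 50 genes go to label
0; modules whose eigengenes (sign-oriented first principal components)
correlate above 0.75 are merged iteratively. The membership-reassignment
step (kME-based) of the reference tool is omitted; module-recovery tests
define correctness here.

## The synthetic study

The generator is the package's study design, fixed once:

* 3 AF + 4 SR donors, 300 nuclei each (cell types at CM 25%, FB 23%,
  the remainder uniform), 500 genes, 800 peaks, 30 motifs — a deliberate
  desk-scale emulation of a ~12,000-nucleus multiome with ~200,000 peaks.
* NB counts with dispersion 0.2 and log-normal(0, 0.3) library sizes;
  marker genes uplifted ×4 in their cell type; a 30 + 30 gene CM AF
  program shifted ×2/×0.5 in AF cardiomyocytes only.
* Two bulk cohorts of 40 + 40 samples sharing the AF program as planted
  DEGs (per-cohort |log2FC| drawn from 0.8–1.5), plus 20 cohort-private
  DEGs each, a binary sex covariate acting on 20 separate genes, and one
  overlapping antisense pair. The 40-per-group size is the scaled-down
  analogue of the real cohorts (80–242 samples each).
* A driver motif whose peaks gain ×3 accessibility in cardiomyocytes and
  a further ×2 in AF cardiomyocytes, with its TF gene planted as an
  AF-upregulated CM marker; peak GC drawn Beta(5, 5) for all peaks so
  background matching is non-trivial.
* Tn5 insertions at 5×10⁻⁴ per bp per nucleus, with shoulder enrichment
  concentrated within 100 bp of driver sites (×3 SR-CM, ×6 AF-CM) and a
  protected ±10 bp core. Concentrating the shoulders is what makes the
  flank-normalized profile informative; insertions spread uniformly to
  ±250 bp would cancel in the normalization.

What the simulation does *not* contain — donor-level random effects,
ambient RNA, doublets, batch structure, mean-variance dispersion trends,
sequence-level Tn5 bias, correlated motif families — bounds what the
passing tests show: they certify the estimators and the integration
logic, not robustness to every artifact of real tissue data. The planted
effects are deliberately strong enough that recovery failures indicate
implementation errors rather than power limits.

## Numerical and degenerate-input conventions

Intervals are 0-based half-open everywhere; `[0,10)` does not touch
`[10,20)`. cCRE ties break by the fixed priority
prom > enhP > enhD > K4m3 > CTCF. The 25% enhancer-atlas rule removes
pairs *strictly below* the threshold. Constant features get AUC 0.5 and
p 1; zero-variance correlations return missing with a flag; all-zero
genes yield missing DE rows excluded from the FDR denominator; groups
smaller than k are skipped with a warning; missing values serialize as
the literal `NA`. All randomized steps (generators, background sampling,
control-gene draws, meta-cell traversal) take explicit seeds, and a
pipeline rerun with the same configuration is byte-identical.

## Known limitations

Dispersion estimation has no shrinkage, so very small pseudobulk designs
(2–4 donors per condition) rely on the strong planted effects; the static
tree cut trades adaptivity for determinism and is not guaranteed to match
dynamic cutting on real data; the greedy meta-cell pass makes no attempt
to maximize the number of meta-cells; and motif membership is binary,
ignoring match scores.
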