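# afcellsig

Cell-type resolution of atrial fibrillation (AF) expression programs from
paired single-nucleus and bulk RNA-seq data.

## The problem

Bulk RNA-seq of left atrial appendages from persistent-AF and sinus-rhythm
(SR) donors finds robust differentially expressed genes (DEGs), but cannot
say *which cell type* drives each change, nor which transcription factors
(TFs) orchestrate them. Single-nucleus multiome assays (paired snRNA-seq +
snATAC-seq on the same nuclei) have the cellular resolution but small donor
numbers. `afcellsig` implements the integrative workflow that combines the
two:

1. **Cross-cohort bulk DE** — per-gene negative-binomial GLM with log link
   and median-of-ratios size-factor offsets; Wald test on the condition
   coefficient with Benjamini–Hochberg FDR; genes kept only when
   significant with a concordant direction in *both* cohorts. A
   strandedness check flags genes whose apparent signal comes from an
   overlapping antisense partner when strand information is dropped.
2. **Cell-type assignment** — pseudobulk (donor × cell type) aggregation of
   the snRNA counts (genes detected in more than 5% of nuclei), the same NB
   Wald test per cell type, and intersection with the concordant bulk DEGs.
3. **Cardiomyocyte AF signature** — genes that are CM-specific
   (one-vs-rest Wilcoxon AUC > 0.5 at FDR < 0.05) *and* differential in
   both bulk cohorts (FDR < 0.05, |log2FC| > 0.25), split into up/down
   sets; nuclei and meta-cells are scored against expression-matched
   control genes (binned-control module score).
4. **Driver TFs** — chromVAR-style motif deviation z-scores with
   GC/accessibility-matched background peaks; KNN meta-cells (30 nuclei,
   ≤ 10 shared, per donor × cell type) aggregated identically across
   modalities; a TF is a *driver candidate* when both its motif activity
   and its expression correlate with the AF signature (FDR < 0.01), and
   TFs are ranked by the product of expression and motif-activity AUCs.
   Tn5 footprint profiles (flank-normalized insertion counts around motif
   sites) visualize binding.
5. **Coexpression modules** — signed WGCNA-style network on merged,
   covariate-residualized bulk cohorts: adjacency
   `((1 + r)/2)^9`, topological overlap, average-linkage clustering with a
   static cut, minimum module size 50, eigengene-correlation merging.
6. **Peak annotation** — half-open interval overlap engine, cCRE
   classification (max-overlap with fixed tie priority), cell-type
   specificity counts, and enhancer-atlas matching with a 25% overlap
   threshold.

Everything runs on a synthetic multiome + two-cohort study with planted
ground truth (markers, a CM AF program, a driver motif, an antisense pair,
protected Tn5 footprints), so the full pipeline is testable offline.

## Worked example

```r
library(afcellsig)

res <- run_pipeline(default_config(seed = 1), out_dir = "af_run")

length(res$concordant$gene_id)      # 61 concordant cross-cohort DEGs
length(res$signature$up_genes)      # 29 genes in the CM AF up-signature
length(res$signature$down_genes)    # 31 genes in the down-signature
subset(res$drivers, joint_flag)     # the planted driver motif M01:
#    tf   r_motif    fdr_motif    r_expr     fdr_expr joint_flag
#   M01 0.9732314 1.641258e-09 0.8961940 3.396999e-05       TRUE
res$tf_rank[1, c("tf", "score")]    # driver TF gene tops the product-of-AUC rank
```

Of the 60 planted AF program genes, 59 survive the cross-cohort
concordance filter and 97% of those are assigned to cardiomyocytes; the
signature recovers the planted program with Jaccard ≈ 0.97 in both
directions. The driver TF is the only one flagged by the dual
motif/expression criterion (r_motif ≈ 0.97 across CM meta-cells), and the
AF-CM footprint shoulder at its motif is ≈ 2× the SR-CM level
(5.1 vs 2.6 flank-normalized insertions).

Every stage writes TSV/MTX artifacts plus a `manifest.yaml`; rerunning
with the same config and seed reproduces all outputs byte for byte.

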