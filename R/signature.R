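#' Build the cell-type-specific AF expression signature
#'
#' Intersects three evidence sets, mirroring the construction of a
#' cardiomyocyte AF signature from one single-nucleus and two bulk cohorts:
#' genes specifically expressed in the target cell type (one-vs-rest AUC
#' strictly greater than `auc_min` at specificity FDR below `spec_fdr`),
#' and differentially expressed in the same direction in both bulk cohorts
#' (FDR below `de_fdr`, absolute log2 fold change above `lfc_min`). The
#' same filters are applied symmetrically for the down signature. All
#' thresholds are recorded in the returned object.
#'
#' @param celltype_auc AUC table for the target cell type
#'   (see [rank_auc_test()]).
#' @param de1,de2 Bulk DE tables (see [nb_glm_de()]).
#' @param auc_min AUC threshold, strictly greater-than (default 0.5).
#' @param spec_fdr Specificity FDR threshold (default 0.05).
#' @param de_fdr Bulk DE FDR threshold (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold, strictly
#'   greater-than (default 0.25).
#' @return list of class `signature_set`: `name`, `up_genes`, `down_genes`,
#'   `thresholds`.
#' @export
build_af_signature <- function(celltype_auc, de1, de2, auc_min = 0.5,
                               spec_fdr = 0.05, de_fdr = 0.05,
                               lfc_min = 0.25) {
  spec_genes <- celltype_auc$feature_id[
    !is.na(celltype_auc$auc) & celltype_auc$auc > auc_min &
      !is.na(celltype_auc$fdr) & celltype_auc$fdr < spec_fdr]
  de_dir <- function(de, dir) {
    ok <- !is.na(de$fdr) & de$fdr < de_fdr & !is.na(de$log2fc) &
      abs(de$log2fc) > lfc_min & sign(de$log2fc) == dir
    de$gene_id[ok]
  }
  up <- Reduce(intersect, list(spec_genes, de_dir(de1, 1), de_dir(de2, 1)))
  down <- Reduce(intersect, list(spec_genes, de_dir(de1, -1),
                                 de_dir(de2, -1)))
  if (!length(up) && !length(down))
    warnf("signature is empty at the given thresholds")
  structure(list(name = unique(celltype_auc$group)[1L],
                 up_genes = sort(up), down_genes = sort(down),
                 thresholds = list(auc_min = auc_min, spec_fdr = spec_fdr,
                                   de_fdr = de_fdr, lfc_min = lfc_min)),
            class = "signature_set")
}

#' Binned-control module score
#'
#' Scores each observation for a gene set against expression-matched
#' controls: all genes are binned into `n_bins` equal-frequency bins by
#' mean expression; each signature gene contributes `n_ctrl` control genes
#' drawn with replacement from its bin (excluding the gene itself when the
#' bin offers alternatives). The score is the mean expression of the
#' signature genes minus the mean over the pooled control draws, per
#' observation. Deterministic given `seed`.
#'
#' @param norm_expr Observations-by-genes normalized expression matrix.
#' @param gene_set Character vector of signature genes (must be present).
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed RNG seed for the control draws.
#' @return Numeric vector of scores, one per observation, named.
#' @export
module_score <- function(norm_expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  if (!length(gene_set)) stopf("gene_set is empty")
  missing <- setdiff(gene_set, colnames(norm_expr))
  if (length(missing))
    stopf("gene(s) absent from the matrix: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  gene_means <- Matrix::colMeans(norm_expr)
  breaks <- unique(stats::quantile(gene_means,
                                   probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(gene_means, breaks = breaks, include.lowest = TRUE,
              labels = FALSE)
  names(bins) <- colnames(norm_expr)
  ctrl_counts <- with_seed(seed, {
    tally <- integer(ncol(norm_expr))
    names(tally) <- colnames(norm_expr)
    for (g in gene_set) {
      pool <- names(bins)[bins == bins[[g]]]
      if (length(pool) > 1) pool <- setdiff(pool, g)
      draw <- pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
      tab <- table(draw)
      tally[names(tab)] <- tally[names(tab)] + as.integer(tab)
    }
    tally
  })
  sig_mean <- Matrix::rowMeans(norm_expr[, gene_set, drop = FALSE])
  used <- ctrl_counts > 0
  ctrl_mean <- as.numeric(norm_expr[, used, drop = FALSE] %*%
                            ctrl_counts[used]) / sum(ctrl_counts)
  stats::setNames(sig_mean - ctrl_mean, rownames(norm_expr))
}

#' Rank candidate target genes by the product of two AUCs
#'
#' Combines cell-type specificity (AUC of the gene in the target cell type
#' vs other cell types) and disease specificity (AUC in AF meta-cells vs
#' all other meta-cells of that cell type): `score = auc_celltype *
#' auc_condition`, ranked descending over the up-signature genes. Ties are
#' broken lexicographically by gene id; a signature gene missing from
#' either AUC table is ranked last and flagged.
#'
#' @param celltype_auc,condition_auc AUC tables covering the signature.
#' @param signature A `signature_set` (see [build_af_signature()]).
#' @return data.frame `gene_id`, `auc_celltype`, `auc_condition`, `score`,
#'   `rank`, `missing`.
#' @export
rank_target_genes <- function(celltype_auc, condition_auc, signature) {
  genes <- sort(signature$up_genes)
  a1 <- celltype_auc$auc[match(genes, celltype_auc$feature_id)]
  a2 <- condition_auc$auc[match(genes, condition_auc$feature_id)]
  score <- a1 * a2
  miss <- is.na(score)
  o <- order(miss, -ifelse(miss, -Inf, score), genes)
  out <- data.frame(gene_id = genes, auc_celltype = a1, auc_condition = a2,
                    score = score, missing = miss,
                    stringsAsFactors = FALSE)[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
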