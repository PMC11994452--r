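#' Correlate a signature score with predictors across meta-cells
#'
#' Pearson correlation (with two-sided p-value) between the per-meta-cell
#' signature score and every predictor column (TF motif z-scores or TF
#' expression), with Benjamini-Hochberg correction across predictors.
#' Meta-cells named in `exclude` are removed first — the outlier exclusion
#' is an explicit input, mirroring removal on clinical rather than
#' algorithmic grounds. Zero-variance predictors are reported missing.
#'
#' @param scores Named numeric vector of per-meta-cell signature scores.
#' @param predictors Meta-cells-by-predictors matrix (rownames must cover
#'   the score names).
#' @param exclude Character vector of meta-cell ids to drop.
#' @return data.frame `predictor`, `r`, `p`, `fdr`, `zero_variance`.
#' @export
correlate_with_signature <- function(scores, predictors,
                                     exclude = character()) {
  keep <- setdiff(names(scores), exclude)
  if (length(keep) < 3)
    stopf("fewer than 3 meta-cells remain after exclusion")
  s <- scores[keep]
  pm <- predictors[keep, , drop = FALSE]
  res <- lapply(seq_len(ncol(pm)), function(j) {
    x <- pm[, j]
    if (anyNA(x))
      return(data.frame(r = NA_real_, p = NA_real_, zero_variance = FALSE))
    cc <- pearson_corr(x, s)
    data.frame(r = cc$r, p = cc$p, zero_variance = cc$zero_variance)
  })
  res <- do.call(rbind, res)
  data.frame(predictor = colnames(pm), r = res$r, p = res$p,
             fdr = bh_fdr(res$p), zero_variance = res$zero_variance,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select driver transcription factors by dual evidence
#'
#' Flags TFs whose motif activity *and* expression both correlate with the
#' signature at FDR below `fdr_max`. The sign of each correlation is
#' retained: anti-correlation counts as evidence (a repressive or
#' down-regulated driver). TFs present in only one arm are excluded with a
#' note column.
#'
#' @param corr_motif,corr_expr Tables from [correlate_with_signature()],
#'   indexed by TF in the `predictor` column.
#' @param fdr_max Joint FDR threshold (default 0.01).
#' @return data.frame `tf`, `r_motif`, `fdr_motif`, `r_expr`, `fdr_expr`,
#'   `joint_flag`, sorted by decreasing |r_motif|.
#' @export
select_driver_tfs <- function(corr_motif, corr_expr, fdr_max = 0.01) {
  common <- intersect(corr_motif$predictor, corr_expr$predictor)
  only <- setdiff(union(corr_motif$predictor, corr_expr$predictor), common)
  if (length(only))
    message(sprintf("%d TF(s) present in one arm only; excluded",
                    length(only)))
  i1 <- match(common, corr_motif$predictor)
  i2 <- match(common, corr_expr$predictor)
  out <- data.frame(tf = common,
                    r_motif = corr_motif$r[i1],
                    fdr_motif = corr_motif$fdr[i1],
                    r_expr = corr_expr$r[i2],
                    fdr_expr = corr_expr$fdr[i2],
                    stringsAsFactors = FALSE)
  out$joint_flag <- !is.na(out$fdr_motif) & !is.na(out$fdr_expr) &
    out$fdr_motif < fdr_max & out$fdr_expr < fdr_max
  out[order(-abs(out$r_motif)), , drop = FALSE]
}

#' Rank transcription factors by joint expression/motif specificity
#'
#' For one cell type: `score = auc_gene * auc_motif`, where `auc_gene` is
#' the one-vs-rest AUC of the TF's expression and `auc_motif` that of its
#' motif deviation z-score. Descending rank, ties broken by TF id; TFs
#' missing a motif AUC are excluded with a note.
#'
#' @param gene_auc AUC table for TF expression in the cell type, with
#'   `feature_id` equal to the TF name.
#' @param motif_auc AUC table for motif z-scores in the same cell type.
#' @param tf_motif_map Named character vector mapping motif id -> TF name
#'   (identity mapping assumed when `NULL`).
#' @return data.frame `tf`, `auc_gene`, `auc_motif`, `score`, `rank`.
#' @export
rank_tfs_by_specificity <- function(gene_auc, motif_auc,
                                    tf_motif_map = NULL) {
  if (is.null(tf_motif_map))
    tf_motif_map <- stats::setNames(motif_auc$feature_id,
                                    motif_auc$feature_id)
  tfs <- intersect(gene_auc$feature_id, unname(tf_motif_map))
  dropped <- setdiff(gene_auc$feature_id, tfs)
  motif_of <- stats::setNames(names(tf_motif_map), tf_motif_map)
  a_gene <- gene_auc$auc[match(tfs, gene_auc$feature_id)]
  a_motif <- motif_auc$auc[match(motif_of[tfs], motif_auc$feature_id)]
  ok <- !is.na(a_motif)
  if (length(dropped) || any(!ok))
    message(sprintf("%d TF(s) without a motif AUC; excluded",
                    length(dropped) + sum(!ok)))
  out <- data.frame(tf = tfs[ok], auc_gene = a_gene[ok],
                    auc_motif = a_motif[ok],
                    score = a_gene[ok] * a_motif[ok],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$tf), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
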