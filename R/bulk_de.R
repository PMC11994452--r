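#' Median-of-ratios size factors
#'
#' The classic normalization for count matrices: a pseudo-reference sample
#' is formed as the per-gene geometric mean over samples (restricted to
#' genes with positive counts in every sample), and each sample's factor is
#' the median of its count ratios to that reference.
#'
#' @param counts Samples-by-genes count matrix (dense or sparse).
#' @return Positive numeric vector of per-sample size factors, named.
#' @export
size_factors <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2) stopf("need at least 2 samples")
  all_pos <- colSums(m > 0) == nrow(m)
  if (!any(all_pos))
    stopf("no gene has positive counts in every sample; cannot form the %s",
          "median-of-ratios reference")
  lm <- log(m[, all_pos, drop = FALSE])
  ref <- colMeans(lm)
  sf <- apply(lm, 1L, function(r) exp(stats::median(r - ref)))
  stats::setNames(sf, rownames(m))
}

#' Negative-binomial GLM differential expression (Wald test)
#'
#' Per-gene NB regression with log link and log size-factor offsets: the
#' mean model is `log mu = X beta + log sf`, dispersion is estimated per
#' gene by method of moments on normalized counts
#' (`alpha = max((s^2 - m) / m^2, 1e-8)`, so variance is `m + alpha m^2`),
#' and the condition coefficient is tested with a Wald z statistic
#' (normal reference). Reported `log2fc` is the unshrunk maximum-likelihood
#' estimate. Genes with all-zero counts get a missing row and are excluded
#' from the Benjamini-Hochberg correction.
#'
#' @param counts Samples-by-genes count matrix.
#' @param sample_table data.frame with `sample_id`, `condition` (`AF`/`SR`)
#'   and any covariate columns; rows must match the matrix rows.
#' @param covariates Character vector of covariate column names to adjust
#'   for (e.g. `"sex"`).
#' @param dispersion Optional fixed dispersion (scalar or per-gene vector)
#'   overriding the moments estimate; `dispersion -> 0` recovers the
#'   Poisson GLM.
#' @return data.frame (one row per gene): `gene_id`, `base_mean`, `log2fc`
#'   (AF vs SR), `se`, `stat`, `p`, `fdr`.
#' @export
nb_glm_de <- function(counts, sample_table, covariates = character(),
                      dispersion = NULL) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) rownames(m) <- sample_table$sample_id
  idx <- match(rownames(m), sample_table$sample_id)
  if (anyNA(idx)) stopf("sample_table does not cover all matrix rows")
  st <- sample_table[idx, , drop = FALSE]
  if (length(unique(st$condition)) < 2)
    stopf("condition must take both values")
  if (min(table(st$condition)) < 2)
    stopf("need >= 2 samples per condition")
  cond <- factor(st$condition, levels = c("SR", "AF"))
  dat <- data.frame(condition = cond)
  for (cv in covariates) {
    if (is.null(st[[cv]])) stopf("covariate '%s' missing from sample_table", cv)
    dat[[cv]] <- st[[cv]]
  }
  X <- stats::model.matrix(
    stats::as.formula(paste(c("~ condition", covariates), collapse = " + ")),
    dat)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("design matrix is not full rank; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  coef_idx <- which(colnames(X) == "conditionAF")

  sf <- size_factors(m)
  norm <- m / sf
  base_mean <- colMeans(norm)
  # dispersion by method of moments within each condition group, pooled,
  # so the condition effect itself does not inflate the estimate
  if (is.null(dispersion)) {
    alpha_by_group <- vapply(levels(cond), function(g) {
      sub <- norm[cond == g, , drop = FALSE]
      mu_g <- colMeans(sub)
      s2_g <- apply(sub, 2L, stats::var)
      (s2_g - mu_g) / pmax(mu_g, 1e-300)^2
    }, numeric(ncol(m)))
    alpha <- pmax(rowMeans(alpha_by_group), 1e-8)
  } else {
    alpha <- pmax(rep_len(dispersion, ncol(m)), 1e-8)
  }
  off <- log(sf)

  fit_gene <- function(j) {
    y <- m[, j]
    if (all(y == 0)) return(c(NA_real_, NA_real_))
    fam <- MASS::negative.binomial(theta = 1 / alpha[[j]])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_))
    info <- crossprod(X, fit$weights * X)  # Fisher information at the MLE
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov)) return(c(NA_real_, NA_real_))
    c(fit$coefficients[[coef_idx]], sqrt(cov[coef_idx, coef_idx]))
  }
  est <- vapply(seq_len(ncol(m)), fit_gene, numeric(2))
  beta <- est[1L, ]; se <- est[2L, ]
  stat <- beta / se
  p <- 2 * stats::pnorm(-abs(stat))
  data.frame(gene_id = colnames(m), base_mean = base_mean,
             log2fc = beta / log(2), se = se / log(2), stat = stat,
             p = p, fdr = bh_fdr(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Aggregate single-nucleus counts to donor-by-cell-type pseudobulk
#'
#' Counts are summed per donor within each cell type. Genes detected in no
#' more than `min_frac` of that cell type's nuclei are dropped from that
#' cell type's table (default: keep genes found in more than 5% of nuclei).
#' Cell types with fewer than 2 donors per condition are flagged untestable.
#'
#' @param gene_counts Nuclei-by-genes sparse count matrix.
#' @param nuc_table Nucleus metadata covering every matrix row.
#' @param min_frac Detection-fraction threshold (strictly-greater kept).
#' @return Named list per cell type: `counts` (donors-by-genes integer
#'   matrix), `samples` (donor metadata with condition), `testable`.
#' @export
pseudobulk_aggregate <- function(gene_counts, nuc_table, min_frac = 0.05) {
  idx <- match(rownames(gene_counts), nuc_table$nucleus_id)
  if (anyNA(idx)) stopf("nucleus table does not cover all matrix rows")
  nt <- nuc_table[idx, , drop = FALSE]
  out <- list()
  for (ct in sort(unique(nt$cell_type))) {
    sel <- which(nt$cell_type == ct)
    sub <- gene_counts[sel, , drop = FALSE]
    detected <- Matrix::colMeans(sub > 0)
    keep <- detected > min_frac
    donors <- nt$donor_id[sel]
    agg <- rowsum(as.matrix(sub[, keep, drop = FALSE]), group = donors)
    cond <- nt$condition[sel][match(rownames(agg), donors)]
    samples <- data.frame(sample_id = rownames(agg), condition = cond,
                          stringsAsFactors = FALSE)
    testable <- all(table(factor(cond, levels = c("AF", "SR"))) >= 2)
    out[[ct]] <- list(counts = agg, samples = samples, testable = testable)
  }
  out
}

#' Cross-cohort concordant differentially expressed genes
#'
#' Default (`mode = "both"`): genes with FDR below the threshold in *both*
#' cohorts and the same sign of log2 fold change. The alternative reading
#' (`mode = "either"`) requires significance in at least one cohort with a
#' concordant sign in the other.
#'
#' @param de1,de2 DE result tables (see [nb_glm_de()]).
#' @param fdr FDR threshold (default 0.05).
#' @param mode `"both"` (default) or `"either"`.
#' @return data.frame `gene_id`, `sign` (+1/-1), `log2fc1`, `log2fc2`,
#'   `fdr1`, `fdr2`.
#' @export
concordant_degs <- function(de1, de2, fdr = 0.05,
                            mode = c("both", "either")) {
  mode <- match.arg(mode)
  common <- intersect(de1$gene_id, de2$gene_id)
  if (length(common) == 0) {
    warnf("no genes shared between the two DE tables")
    return(data.frame(gene_id = character(), sign = numeric(),
                      log2fc1 = numeric(), log2fc2 = numeric(),
                      fdr1 = numeric(), fdr2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  i1 <- match(common, de1$gene_id); i2 <- match(common, de2$gene_id)
  f1 <- de1$fdr[i1]; f2 <- de2$fdr[i2]
  l1 <- de1$log2fc[i1]; l2 <- de2$log2fc[i2]
  sig <- if (mode == "both") !is.na(f1) & !is.na(f2) & f1 < fdr & f2 < fdr
  else !is.na(f1) & !is.na(f2) & (f1 < fdr | f2 < fdr)
  concordant <- sig & !is.na(l1) & !is.na(l2) & sign(l1) == sign(l2) &
    sign(l1) != 0
  data.frame(gene_id = common[concordant], sign = sign(l1[concordant]),
             log2fc1 = l1[concordant], log2fc2 = l2[concordant],
             fdr1 = f1[concordant], fdr2 = f2[concordant],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign concordant bulk DEGs to cell types via pseudobulk DE
#'
#' For each concordant bulk DEG, lists every cell type in which the gene is
#' significant at the FDR threshold in the per-cell-type pseudobulk DE with
#' the same direction of effect as in bulk. Genes significant in no cell
#' type are retained with an empty assignment.
#'
#' @param bulk_concordant Output of [concordant_degs()].
#' @param per_celltype_de Named list cell type -> DE result table.
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame `gene_id`, `sign`, `cell_types` (list column),
#'   `n_celltypes`.
#' @export
assign_degs_to_celltypes <- function(bulk_concordant, per_celltype_de,
                                     fdr = 0.05) {
  assignments <- lapply(seq_len(nrow(bulk_concordant)), function(i) {
    g <- bulk_concordant$gene_id[[i]]
    s <- bulk_concordant$sign[[i]]
    hits <- character()
    for (ct in names(per_celltype_de)) {
      de <- per_celltype_de[[ct]]
      j <- match(g, de$gene_id)
      if (is.na(j)) next
      if (!is.na(de$fdr[[j]]) && de$fdr[[j]] < fdr &&
          !is.na(de$log2fc[[j]]) && sign(de$log2fc[[j]]) == s)
        hits <- c(hits, ct)
    }
    hits
  })
  data.frame(gene_id = bulk_concordant$gene_id,
             sign = bulk_concordant$sign,
             cell_types = I(assignments),
             n_celltypes = lengths(assignments),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag strandedness artifacts at overlapping antisense gene pairs
#'
#' When quantification ignores strand, reads from a truly differential gene
#' are credited to its overlapping opposite-strand partner, which then
#' appears significant. This check flags genes of the supplied antisense
#' pairs that are significant in the unstranded analysis but not in the
#' stranded one.
#'
#' @param de_stranded,de_unstranded DE tables from the same samples.
#' @param antisense_pairs data.frame with columns `gene_plus`, `gene_minus`.
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame `gene_id`, `partner`, `fdr_stranded`,
#'   `fdr_unstranded`, `flagged`.
#' @export
strand_artifact_check <- function(de_stranded, de_unstranded,
                                  antisense_pairs, fdr = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(antisense_pairs))) {
    pair <- c(antisense_pairs$gene_plus[[i]], antisense_pairs$gene_minus[[i]])
    if (!all(pair %in% de_stranded$gene_id) ||
        !all(pair %in% de_unstranded$gene_id)) {
      warnf("antisense pair (%s, %s) absent from DE tables; skipped",
            pair[[1L]], pair[[2L]])
      next
    }
    for (k in 1:2) {
      g <- pair[[k]]; partner <- pair[[3L - k]]
      fs <- de_stranded$fdr[[match(g, de_stranded$gene_id)]]
      fu <- de_unstranded$fdr[[match(g, de_unstranded$gene_id)]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, partner = partner, fdr_stranded = fs,
        fdr_unstranded = fu,
        flagged = isTRUE(fu < fdr) && !isTRUE(fs < fdr),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), partner = character(),
                      fdr_stranded = numeric(), fdr_unstranded = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
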