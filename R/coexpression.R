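#' Prefilter genes for network construction
#'
#' Keeps genes from a merged-cohort DE table with base mean expression
#' strictly above `base_mean_min`, absolute log2 fold change strictly above
#' `lfc_min` and nominal p-value below `p_max`.
#'
#' @param de_merged DE result table (see [nb_glm_de()]).
#' @param base_mean_min,lfc_min,p_max Filter thresholds (defaults 1, 0.05,
#'   0.05).
#' @return Character vector of retained gene ids.
#' @export
prefilter_genes <- function(de_merged, base_mean_min = 1, lfc_min = 0.05,
                            p_max = 0.05) {
  keep <- !is.na(de_merged$base_mean) & de_merged$base_mean > base_mean_min &
    !is.na(de_merged$log2fc) & abs(de_merged$log2fc) > lfc_min &
    !is.na(de_merged$p) & de_merged$p < p_max
  de_merged$gene_id[keep]
}

#' Remove covariate effects from an expression matrix
#'
#' Per-gene least squares on the (centered) covariate design: the fitted
#' covariate terms are subtracted so covariate-group means are equalized
#' while the grand mean is preserved. The condition of interest must *not*
#' be among the covariates.
#'
#' @param expr Samples-by-genes matrix of transformed expression values.
#' @param covariates data.frame or matrix of covariate columns (no
#'   intercept; factors must be pre-coded numerically).
#' @return Corrected matrix, same shape and dimnames.
#' @export
residualize_covariates <- function(expr, covariates) {
  x <- as.matrix(expr)
  C <- as.matrix(covariates)
  if (nrow(C) != nrow(x)) stopf("covariates must have one row per sample")
  Cc <- scale(C, center = TRUE, scale = FALSE)
  if (qr(Cc)$rank < ncol(Cc))
    stopf("covariates are collinear (with the intercept or each other)")
  beta <- solve(crossprod(Cc), crossprod(Cc, x))
  x - Cc %*% beta
}

#' Signed coexpression adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^power`: perfectly correlated genes get
#' adjacency 1, perfectly anti-correlated genes 0 (the "signed" network
#' convention), uncorrelated genes `0.5^power`.
#'
#' @param expr Samples-by-genes matrix.
#' @param power Soft-threshold exponent (default 9).
#' @return Genes-by-genes adjacency in `[0, 1]`, unit diagonal.
#' @export
signed_adjacency <- function(expr, power = 9) {
  x <- as.matrix(expr)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stopf("constant gene(s): %s",
          paste(utils::head(colnames(x)[sds == 0], 5), collapse = ", "))
  a <- ((1 + stats::cor(x)) / 2)^power
  a[a > 1] <- 1; a[a < 0] <- 0
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and connectivity
#' `k_i = sum_{u != i} a_iu`. Values lie in `[0, 1]`; the diagonal is 1.
#' High TOM means two genes share most of their network neighbourhood.
#'
#' @param adjacency Symmetric adjacency from [signed_adjacency()].
#' @return TOM matrix, same shape.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  a0 <- a
  diag(a0) <- 0
  L <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (L + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a static height (`cut_height` as a fraction of the merge-height
#' range). Clusters smaller than `min_module_size` are sent to the
#' unassigned label 0. Modules whose eigengenes correlate above
#' `1 - merge_cut_height` are then merged, iterated to a fixed point.
#'
#' @param tom TOM matrix (see [topological_overlap()]).
#' @param expr Samples-by-genes matrix (eigengene computation for merging).
#' @param min_module_size Smallest allowed module (default 50).
#' @param cut_height Static cut as a fraction of the dendrogram height
#'   range, in (0, 1) (default 0.6).
#' @param merge_cut_height Modules with eigengene correlation above
#'   `1 - merge_cut_height` are merged (default 0.25).
#' @return list with `labels` (named integer vector, 0 = unassigned) and
#'   `eigengenes` (samples-by-modules matrix, columns `ME<label>`).
#' @export
detect_modules <- function(tom, expr, min_module_size = 50,
                           cut_height = 0.6, merge_cut_height = 0.25) {
  if (cut_height <= 0 || cut_height >= 1)
    stopf("cut_height must lie strictly between 0 and 1")
  genes <- colnames(tom)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- hc$height
  cut_at <- min(h) + cut_height * (max(h) - min(h))
  raw <- stats::cutree(hc, h = cut_at)
  labels <- relabel_modules(raw, min_module_size)
  # iterative merge by eigengene correlation
  repeat {
    mods <- setdiff(sort(unique(labels)), 0L)
    if (length(mods) < 2) break
    me <- module_eigengene(expr, labels)
    cm <- stats::cor(me)
    diag(cm) <- -Inf
    best <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    if (max(cm) <= 1 - merge_cut_height) break
    from <- as.integer(sub("^ME", "", colnames(cm)[best[[2L]]]))
    to <- as.integer(sub("^ME", "", rownames(cm)[best[[1L]]]))
    labels[labels == max(from, to)] <- min(from, to)
    labels <- relabel_modules(labels, min_module_size)
  }
  me <- if (any(labels != 0)) module_eigengene(expr, labels) else
    matrix(numeric(), nrow(expr), 0)
  list(labels = stats::setNames(labels, genes), eigengenes = me)
}

# Renumber modules 1..K by decreasing size; undersized clusters -> 0.
relabel_modules <- function(labels, min_module_size) {
  tab <- table(labels)
  keep <- names(tab)[tab >= min_module_size]
  labels[!(labels %in% as.integer(keep))] <- 0L
  mods <- setdiff(names(sort(table(labels[labels != 0]), decreasing = TRUE)),
                  "0")
  new <- stats::setNames(seq_along(mods), mods)
  out <- integer(length(labels))
  nz <- labels != 0
  out[nz] <- new[as.character(labels[nz])]
  out
}

#' Module eigengenes
#'
#' First principal component of each module's standardized expression,
#' sign-oriented to correlate positively with the module's mean expression
#' profile. A single-gene module returns that gene's standardized profile.
#'
#' @param expr Samples-by-genes matrix.
#' @param labels Integer module labels per gene (0 = unassigned, skipped),
#'   aligned with `colnames(expr)` order (names used when present).
#' @return Samples-by-modules matrix with columns `ME<label>`.
#' @export
module_eigengene <- function(expr, labels) {
  x <- as.matrix(expr)
  if (!is.null(names(labels))) {
    idx <- match(names(labels), colnames(x))
    if (anyNA(idx)) stopf("labels name genes absent from the matrix")
  } else {
    idx <- seq_along(labels)
  }
  mods <- setdiff(sort(unique(labels)), 0L)
  me <- matrix(NA_real_, nrow(x), length(mods),
               dimnames = list(rownames(x), paste0("ME", mods)))
  for (j in seq_along(mods)) {
    cols <- idx[labels == mods[[j]]]
    xs <- scale(x[, cols, drop = FALSE])
    if (ncol(xs) == 1L) {
      me[, j] <- xs[, 1L]
      next
    }
    sv <- svd(xs, nu = 1L, nv = 0L)
    eg <- sv$u[, 1L] * sv$d[1L] / sqrt(max(1, nrow(xs) - 1))
    if (stats::cor(eg, rowMeans(xs)) < 0) eg <- -eg
    me[, j] <- eg
  }
  me
}
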