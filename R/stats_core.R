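#' Library-size log-normalization
#'
#' `value = ln(1 + scale * c / rowTotal)`, the standard single-cell
#' normalization feeding the AUC and module-score steps. Zeros map to zero,
#' so sparsity is preserved.
#'
#' @param counts Observations-by-features sparse count matrix.
#' @param scale Scale factor (default `1e4`).
#' @return Sparse matrix of normalized values, same shape and dimnames.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  counts <- as_sparse(counts)
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stopf("observation(s) with zero total counts: %s",
          paste(utils::head(rownames(counts)[totals == 0], 5), collapse = ", "))
  out <- counts
  tm <- methods::as(counts, "TsparseMatrix")
  out@x <- log1p(scale * tm@x / totals[tm@i + 1L])
  out
}

#' One-vs-rest Wilcoxon rank-sum AUC test
#'
#' For each feature, compares observations in group `g` against all other
#' observations with a Wilcoxon rank-sum test using midranks for ties.
#' `AUC = U / (n1 * n2)` where `U` is the Mann-Whitney statistic of the
#' in-group; 1 means every in-group value exceeds every out-group value,
#' 0.5 is uninformative. The two-sided p-value uses the normal approximation
#' with tie-corrected variance (no continuity correction); FDR is
#' Benjamini-Hochberg across features within this one group contrast.
#'
#' @param values Observations-by-features matrix (dense or sparse) of
#'   normalized values.
#' @param groups Group label per observation.
#' @param g The in-group label to contrast against the rest.
#' @return data.frame with columns `feature_id`, `group`, `auc`, `p`, `fdr`,
#'   `pct_in`, `pct_out`.
#' @export
rank_auc_test <- function(values, groups, g) {
  rank_auc_all(values, groups, which_groups = g)
}

#' One-vs-rest Wilcoxon AUC for every group at once
#'
#' Same contrast as [rank_auc_test()], computed for each requested group.
#' Ranks (and the tie-correction term) are shared across contrasts, so this
#' is the fast path for per-cell-type specificity scans. FDR is computed
#' within each group contrast across features, never pooled across groups.
#'
#' @inheritParams rank_auc_test
#' @param which_groups Groups to test (default: all labels present).
#' @return data.frame as in [rank_auc_test()], rows stacked by group.
#' @export
rank_auc_all <- function(values, groups, which_groups = NULL) {
  groups <- as.character(groups)
  if (length(groups) != nrow(values))
    stopf("length(groups) must equal nrow(values)")
  if (is.null(which_groups)) which_groups <- sort(unique(groups))
  vals <- as.matrix(values)
  n <- nrow(vals)
  ranks <- apply(vals, 2L, rank)
  tie_term <- apply(ranks, 2L, function(r) {
    tab <- tabulate(match(r, unique(r)))
    sum(tab^3 - tab)
  })
  nz <- vals != 0
  out <- lapply(which_groups, function(g) {
    in_g <- groups == g
    n1 <- sum(in_g); n2 <- n - n1
    if (n1 == 0) stopf("group '%s' has no members", g)
    if (n2 == 0) stopf("group '%s' has an empty complement", g)
    u <- colSums(ranks[in_g, , drop = FALSE]) - n1 * (n1 + 1) / 2
    auc <- u / (n1 * n2)
    v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- ifelse(v > 0, (u - n1 * n2 / 2) / sqrt(pmax(v, .Machine$double.eps)),
                0)
    p <- ifelse(v > 0, 2 * stats::pnorm(-abs(z)), 1)
    auc[v <= 0] <- 0.5
    data.frame(feature_id = colnames(vals), group = g, auc = auc, p = p,
               fdr = bh_fdr(p),
               pct_in = colMeans(nz[in_g, , drop = FALSE]),
               pct_out = colMeans(nz[!in_g, , drop = FALSE]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_i = min_{j : p_(j) >= p_(i)} p_(j) * m / j`, with `m` the number of
#' non-missing p-values; missing values are propagated and excluded from
#' `m`. Order-preserving and never smaller than `p`.
#'
#' @param p Vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) return(q)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  qv <- pmin(1, cummin(pv[o] * m / (m:1)))
  tmp <- numeric(m)
  tmp[o] <- qv
  q[ok] <- tmp
  q
}

#' Pearson correlation with a two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, with
#' `p = 0` at `r = +/-1`. Zero variance in either input yields a missing
#' correlation with `zero_variance = TRUE`.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return list with elements `r`, `p`, `zero_variance`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) stopf("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, zero_variance = TRUE))
  r <- sum(scale(x, scale = FALSE) * scale(y, scale = FALSE)) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, zero_variance = FALSE)
}
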