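#' PCA embedding of normalized expression
#'
#' Centers and unit-variance-scales each feature, then projects the
#' observations on the top right-singular vectors. Zero-variance features
#' are dropped before scaling.
#'
#' @param norm_expr Observations-by-features matrix of normalized values.
#' @param n_components Number of components to keep (default 10).
#' @return Observations-by-components coordinate matrix; singular values
#'   are attached as attribute `sdev`, loadings as `rotation`.
#' @export
pca_embed <- function(norm_expr, n_components = 10) {
  x <- as.matrix(norm_expr)
  keep <- apply(x, 2L, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rank_est <- sum(pc$sdev > pc$sdev[1L] * 1e-8)
  if (n_components > rank_est)
    stopf("n_components (%d) exceeds the rank of the data (%d)",
          n_components, rank_est)
  pc$x <- pc$x[, seq_len(n_components), drop = FALSE]
  pc$rotation <- pc$rotation[, seq_len(n_components), drop = FALSE]
  emb <- pc$x
  rownames(emb) <- rownames(norm_expr)
  attr(emb, "sdev") <- pc$sdev[seq_len(n_components)]
  attr(emb, "rotation") <- pc$rotation
  emb
}

#' Greedy KNN meta-cell construction within donor-by-cell-type groups
#'
#' Within each donor-by-cell-type group holding at least `k` nuclei, builds
#' the k-nearest-neighbour graph (Euclidean distance in the embedding, the
#' seed nucleus counted among its own `k` members), visits seed nuclei in a
#' seeded random order, and emits a seed's neighbourhood as a meta-cell if
#' and only if it shares at most `max_shared` nuclei with every meta-cell
#' already emitted in that group. Groups smaller than `k` are skipped with
#' a warning. Deterministic given `seed`.
#'
#' @param embedding Observations-by-components matrix (see [pca_embed()]).
#' @param nuc_table Nucleus metadata covering every embedding row.
#' @param k Meta-cell size (default 30).
#' @param max_shared Maximum pairwise overlap between meta-cells
#'   (default 10).
#' @param seed RNG seed for the traversal order.
#' @return data.frame `metacell_id`, `nucleus_id`, `donor_id`, `cell_type`,
#'   `condition`; each meta-cell contributes exactly `k` rows.
#' @export
make_metacells <- function(embedding, nuc_table, k = 30, max_shared = 10,
                           seed = 1L) {
  if (k <= 0) stopf("k must be positive")
  idx <- match(rownames(embedding), nuc_table$nucleus_id)
  if (anyNA(idx)) stopf("nucleus table does not cover all embedding rows")
  nt <- nuc_table[idx, , drop = FALSE]
  groups <- split(seq_len(nrow(nt)),
                  paste(nt$donor_id, nt$cell_type, sep = "||"))
  out <- list()
  with_seed(seed, {
    for (gname in sort(names(groups))) {
      rows <- groups[[gname]]
      if (length(rows) < k) {
        warnf("group %s has %d nuclei (< k = %d); skipped",
              gname, length(rows), k)
        next
      }
      d <- as.matrix(stats::dist(embedding[rows, , drop = FALSE]))
      # k-neighbourhood of each nucleus, self included
      nbrs <- matrix(apply(d, 1L, function(dr) order(dr)[seq_len(k)]),
                     nrow = k)
      emitted <- list()
      for (s in sample(seq_along(rows))) {
        cand <- nbrs[, s]
        ok <- all(vapply(emitted, function(e)
          sum(cand %in% e) <= max_shared, logical(1)))
        if (ok) emitted[[length(emitted) + 1L]] <- cand
      }
      donor <- nt$donor_id[rows[1L]]
      ct <- nt$cell_type[rows[1L]]
      cond <- nt$condition[rows[1L]]
      for (i in seq_along(emitted)) {
        mc_id <- sprintf("%s.%s.mc%02d", donor, ct, i)
        out[[length(out) + 1L]] <- data.frame(
          metacell_id = mc_id,
          nucleus_id = nt$nucleus_id[rows[emitted[[i]]]],
          donor_id = donor, cell_type = ct, condition = cond,
          stringsAsFactors = FALSE)
      }
    }
  })
  if (!length(out))
    return(data.frame(metacell_id = character(), nucleus_id = character(),
                      donor_id = character(), cell_type = character(),
                      condition = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Aggregate a count matrix over a meta-cell assignment
#'
#' Sums member-nucleus counts per meta-cell. Applying the same assignment
#' verbatim to the gene and peak matrices keeps the two modalities
#' consistent.
#'
#' @param counts Nuclei-by-features matrix.
#' @param assignment Output of [make_metacells()].
#' @return Meta-cells-by-features dense matrix.
#' @export
aggregate_matrix <- function(counts, assignment) {
  missing <- setdiff(assignment$nucleus_id, rownames(counts))
  if (length(missing))
    stopf("assignment member(s) missing from the matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  sel <- counts[assignment$nucleus_id, , drop = FALSE]
  rowsum(as.matrix(sel), group = assignment$metacell_id)
}

#' Per-meta-cell metadata from an assignment
#'
#' @param assignment Output of [make_metacells()].
#' @return One row per meta-cell: `metacell_id`, `donor_id`, `cell_type`,
#'   `condition`.
#' @export
metacell_info <- function(assignment) {
  info <- unique(assignment[, c("metacell_id", "donor_id", "cell_type",
                                "condition")])
  rownames(info) <- NULL
  info[order(info$metacell_id), , drop = FALSE]
}
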