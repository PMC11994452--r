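#' All overlapping interval pairs (sorted sweep)
#'
#' Finds every pair `(i, j)` with `a_i` intersecting `b_j` under the
#' package-wide 0-based half-open convention: `[0,10)` and `[10,20)` do
#' *not* overlap. Implemented as a per-chromosome sweep over
#' start-sorted intervals; strand is ignored (ATAC peaks are unstranded).
#'
#' @param a,b Interval sets (see [interval_set()]).
#' @return data.frame `query` (index into `a`), `subject` (index into `b`),
#'   `overlap` (intersection length in bp).
#' @export
overlap_intervals <- function(a, b) {
  empty <- data.frame(query = integer(), subject = integer(),
                      overlap = integer())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  out <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    oa <- ia[order(a$start[ia])]
    ob <- ib[order(b$start[ib])]
    sa <- a$start[oa]; ea <- a$end[oa]
    sb <- b$start[ob]; eb <- b$end[ob]
    active <- integer()  # indices into ob of b-intervals not yet outrun
    j <- 1L
    for (k in seq_along(oa)) {
      while (j <= length(ob) && sb[j] < ea[k]) {
        active <- c(active, j)
        j <- j + 1L
      }
      if (length(active)) {
        live <- active[eb[active] > sa[k]]
        active <- live
        hit <- live[sb[live] < ea[k]]
        if (length(hit))
          out[[length(out) + 1L]] <- data.frame(
            query = rep(oa[k], length(hit)), subject = ob[hit],
            overlap = pmin(ea[k], eb[hit]) - pmax(sa[k], sb[hit]))
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

ccre_classes <- c("prom", "enhP", "enhD", "K4m3", "CTCF")

#' Classify ATAC peaks by overlapping cCRE type
#'
#' Each peak is labeled with the class of the candidate cis-regulatory
#' element it overlaps most (by intersection length); ties are broken by
#' the fixed priority `prom > enhP > enhD > K4m3 > CTCF`. Peaks overlapping
#' no cCRE are labeled `"not.Encode"`.
#'
#' @param peaks Interval set of ATAC peaks.
#' @param ccres Interval set with `label` in
#'   `c("prom", "enhP", "enhD", "K4m3", "CTCF")`.
#' @return Character vector of classes, one per peak.
#' @export
classify_by_ccre <- function(peaks, ccres) {
  if (is.null(ccres$label) || !all(ccres$label %in% ccre_classes))
    stopf("cCRE labels must be among: %s",
          paste(ccre_classes, collapse = ", "))
  hits <- overlap_intervals(peaks, ccres)
  cls <- rep("not.Encode", nrow(peaks))
  if (nrow(hits)) {
    hits$class <- ccres$label[hits$subject]
    hits$priority <- match(hits$class, ccre_classes)
    hits <- hits[order(hits$query, -hits$overlap, hits$priority), ,
                 drop = FALSE]
    best <- hits[!duplicated(hits$query), , drop = FALSE]
    cls[best$query] <- best$class
  }
  cls
}

#' Peak cell-type-specificity counts and cCRE class composition
#'
#' For each unified peak, counts the number of cell types whose
#' per-cell-type peak calls overlap it (any-overlap rule), then summarizes,
#' for each count `n`, the fraction of peaks in each cCRE class (fractions
#' sum to 1 within each `n`). A peak called in exactly one cell type is
#' "cell-type specific".
#'
#' @param per_celltype_calls Named list: cell type -> interval set of calls.
#' @param unified_peaks Interval set of unified peaks.
#' @param classes Character vector of cCRE classes per unified peak (see
#'   [classify_by_ccre()]).
#' @return list with `per_peak` (data.frame `peak`, `n_celltypes`, `class`)
#'   and `summary` (data.frame `n_celltypes`, `class`, `fraction`).
#' @export
specificity_by_celltype_counts <- function(per_celltype_calls,
                                           unified_peaks, classes) {
  n_ct <- integer(nrow(unified_peaks))
  for (ct in names(per_celltype_calls)) {
    calls <- per_celltype_calls[[ct]]
    if (nrow(calls) == 0) {
      warnf("cell type '%s' has an empty call set", ct)
      next
    }
    hit <- unique(overlap_intervals(unified_peaks, calls)$query)
    n_ct[hit] <- n_ct[hit] + 1L
  }
  per_peak <- data.frame(peak = seq_len(nrow(unified_peaks)),
                         n_celltypes = n_ct, class = classes,
                         stringsAsFactors = FALSE)
  tab <- table(per_peak$n_celltypes, per_peak$class)
  frac <- prop.table(tab, margin = 1L)
  summary <- as.data.frame(frac, stringsAsFactors = FALSE)
  names(summary) <- c("n_celltypes", "class", "fraction")
  summary$n_celltypes <- as.integer(as.character(summary$n_celltypes))
  list(per_peak = per_peak, summary = summary)
}

#' Match cell-type peak sets against an enhancer atlas
#'
#' `fraction(ct, atlas_ct)` is the share of the cell type's peaks that
#' overlap the atlas cell type's element set. Pairs with a fraction
#' strictly below `threshold` are dropped from the filtered output (a
#' fraction exactly at the threshold is kept); the full matrix is always
#' returned. Cell types with zero peaks get an undefined (NA) row.
#'
#' @param celltype_peaks Named list: cell type -> interval set.
#' @param atlas_sets Named list: atlas cell type -> interval set.
#' @param threshold Minimum overlap fraction to keep a pair (default 0.25).
#' @return list with `fractions` (matrix cell types x atlas cell types) and
#'   `pairs` (data.frame of retained pairs `cell_type`, `atlas_cell_type`,
#'   `fraction`).
#' @export
atlas_match_fraction <- function(celltype_peaks, atlas_sets,
                                 threshold = 0.25) {
  if (!length(celltype_peaks) || !length(atlas_sets))
    stopf("both peak maps must be non-empty")
  fr <- matrix(NA_real_, length(celltype_peaks), length(atlas_sets),
               dimnames = list(names(celltype_peaks), names(atlas_sets)))
  for (ct in names(celltype_peaks)) {
    pk <- celltype_peaks[[ct]]
    if (nrow(pk) == 0) {
      warnf("cell type '%s' has zero peaks; fractions undefined", ct)
      next
    }
    for (act in names(atlas_sets)) {
      hit <- unique(overlap_intervals(pk, atlas_sets[[act]])$query)
      fr[ct, act] <- length(hit) / nrow(pk)
    }
  }
  keep <- which(!is.na(fr) & fr >= threshold, arr.ind = TRUE)
  pairs <- data.frame(cell_type = rownames(fr)[keep[, 1L]],
                      atlas_cell_type = colnames(fr)[keep[, 2L]],
                      fraction = fr[keep], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$cell_type, -pairs$fraction), , drop = FALSE]
  rownames(pairs) <- NULL
  list(fractions = fr, pairs = pairs)
}
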