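#' Peak bias covariates and joint bins for background matching
#'
#' Computes the two covariates used to match background peaks: GC content
#' and `ln(1 + mean accessibility)`. Both are z-scored and quantile-binned
#' into `n_bins` equal-frequency bins; the joint bin is the pair of bin
#' indices on the resulting grid.
#'
#' @param peak_counts Observations-by-peaks count matrix.
#' @param peak_gc GC fraction per peak, in `[0, 1]`.
#' @param n_bins Bins per covariate (default 10); collapsed with a warning
#'   when there are fewer peaks than bins.
#' @return data.frame `peak_id`, `gc`, `log_mean_access`, `gc_bin`,
#'   `access_bin`, `joint_bin`; attribute `n_bins` records the grid size.
#' @export
peak_bias <- function(peak_counts, peak_gc, n_bins = 10) {
  if (length(peak_gc) != ncol(peak_counts))
    stopf("peak_gc must have one entry per peak")
  n_peaks <- ncol(peak_counts)
  if (n_peaks < n_bins) {
    warnf("fewer peaks (%d) than bins (%d); collapsing bins", n_peaks, n_bins)
    n_bins <- max(1L, n_peaks)
  }
  lma <- log1p(Matrix::colMeans(peak_counts))
  qbin <- function(v) {
    if (length(unique(v)) == 1L) return(rep(1L, length(v)))
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  gc_bin <- qbin(as.numeric(scale(peak_gc)))
  access_bin <- qbin(as.numeric(scale(lma)))
  out <- data.frame(peak_id = colnames(peak_counts), gc = peak_gc,
                    log_mean_access = lma, gc_bin = gc_bin,
                    access_bin = access_bin,
                    joint_bin = (gc_bin - 1L) * n_bins + access_bin,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_bins") <- n_bins
  out
}

#' Sample bias-matched background peaks
#'
#' For every peak, draws `n_bg` background peaks with replacement,
#' uniformly from the peak's joint bias bin (GC-by-accessibility grid); if
#' a bin were empty for some target, the nearest non-empty bin by grid
#' (Manhattan) distance is used. Self-sampling is allowed. Deterministic
#' given `seed`.
#'
#' @param bias Output of [peak_bias()].
#' @param n_bg Background draws per peak (default 50).
#' @param seed RNG seed.
#' @return Integer matrix (`n_peaks` x `n_bg`) of background peak indices;
#'   rownames are peak ids.
#' @export
sample_background_peaks <- function(bias, n_bg = 50, seed = 1L) {
  n <- nrow(bias)
  if (n == 0) stopf("empty peak set")
  bins <- split(seq_len(n), bias$joint_bin)
  nb <- attr(bias, "n_bins")
  with_seed(seed, {
    bg <- matrix(NA_integer_, nrow = n, ncol = n_bg,
                 dimnames = list(bias$peak_id, NULL))
    for (b in names(bins)) {
      members <- bins[[b]]
      pool <- members
      if (!length(pool)) {
        # nearest non-empty bin on the grid (defensive; own bin has members)
        bi <- as.integer(b)
        gx <- (bi - 1L) %/% nb + 1L; gy <- (bi - 1L) %% nb + 1L
        dists <- vapply(names(bins), function(ob) {
          oi <- as.integer(ob)
          abs((oi - 1L) %/% nb + 1L - gx) + abs((oi - 1L) %% nb + 1L - gy)
        }, numeric(1))
        pool <- bins[[names(which.min(dists))]]
      }
      draws <- pool[sample.int(length(pool), length(members) * n_bg,
                               replace = TRUE)]
      bg[members, ] <- matrix(draws, nrow = length(members))
    }
    bg
  })
}

#' chromVAR-style motif deviation z-scores
#'
#' For motif `m` and observation `i`, the observed accessibility is
#' `X_im = sum over motif peaks of counts`, and the expectation under no
#' motif effect is `E_im = f_i * sum over motif peaks of w_p`, where `f_i`
#' is the observation's total counts and `w_p` the peak's share of the
#' grand total. The raw deviation `(X - E) / E` is corrected by the mean of
#' the same statistic over `n_bg` bias-matched background peak sets, and
#' standardized by their standard deviation to give the z-score. A motif
#' containing all peaks has raw deviation identically zero.
#'
#' @param peak_counts Observations-by-peaks count matrix.
#' @param membership Named list: motif id -> character vector of peak ids.
#' @param backgrounds Background index matrix from
#'   [sample_background_peaks()].
#' @return list with matrices `raw`, `corrected`, `z` (observations by
#'   motifs) and logical vector `zero_sd` flagging motifs whose background
#'   SD vanished somewhere.
#' @export
motif_deviations <- function(peak_counts, membership, backgrounds) {
  counts <- as_sparse(peak_counts)
  peak_ids <- colnames(counts)
  if (!length(membership)) stopf("membership is empty")
  for (m in names(membership)) {
    if (!length(membership[[m]])) stopf("motif '%s' has no peaks", m)
    if (!all(membership[[m]] %in% peak_ids))
      stopf("motif '%s' references unknown peaks", m)
  }
  n_bg <- ncol(backgrounds)
  n_motifs <- length(membership)
  motif_ids <- names(membership)
  f <- Matrix::rowSums(counts)
  cs <- Matrix::colSums(counts)
  grand <- sum(cs)

  # sparse indicator over (observed + n_bg background) motif columns
  blocks <- lapply(seq_along(membership), function(mi) {
    p <- match(membership[[mi]], peak_ids)
    col0 <- (mi - 1L) * (n_bg + 1L) + 1L
    i <- c(p, as.vector(backgrounds[p, , drop = FALSE]))
    j <- c(rep(col0, length(p)),
           rep(col0 + seq_len(n_bg), each = length(p)))
    cbind(i, j)
  })
  trip <- do.call(rbind, blocks)
  S <- Matrix::sparseMatrix(i = trip[, 1L], j = trip[, 2L], x = 1,
                            dims = c(length(peak_ids),
                                     n_motifs * (n_bg + 1L)))
  X <- as.matrix(counts %*% S)
  # integer peak totals are summed before dividing by the grand total, so
  # a motif holding every peak has expectation exactly equal to X
  Ew <- as.numeric(cs %*% S) / grand
  E <- outer(f, Ew)
  dev <- (X - E) / E
  dev[E == 0] <- NA_real_

  obs_cols <- (seq_len(n_motifs) - 1L) * (n_bg + 1L) + 1L
  raw <- dev[, obs_cols, drop = FALSE]
  corrected <- z <- matrix(NA_real_, nrow(raw), n_motifs)
  zero_sd <- logical(n_motifs)
  for (mi in seq_len(n_motifs)) {
    bgdev <- dev[, (mi - 1L) * (n_bg + 1L) + 1L + seq_len(n_bg),
                 drop = FALSE]
    mu <- rowMeans(bgdev)
    sdv <- sqrt(pmax(rowSums((bgdev - mu)^2) / (n_bg - 1L), 0))
    corrected[, mi] <- raw[, mi] - mu
    zi <- corrected[, mi] / sdv
    zi[sdv == 0] <- NA_real_
    zero_sd[mi] <- any(sdv == 0, na.rm = TRUE)
    z[, mi] <- zi
  }
  dn <- list(rownames(counts), motif_ids)
  dimnames(raw) <- dimnames(corrected) <- dimnames(z) <- dn
  list(raw = raw, corrected = corrected, z = z,
       zero_sd = stats::setNames(zero_sd, motif_ids))
}

#' Flank-normalized Tn5 footprint profiles
#'
#' Sums insertion events at each base in `[-window, +window]` around motif
#' site centers (interval midpoints; minus-strand sites are orientation
#' flipped), per nucleus group, and divides by the group's mean count over
#' the flank region so that the flank level is about 1. A protein-bound
#' footprint appears as a dip at the core with elevated shoulders.
#'
#' @param fragments data.frame of insertions (chrom, start, end, barcode).
#' @param motif_sites Interval set of motif sites.
#' @param nucleus_groups Named list: group label -> nucleus barcodes.
#' @param window Half-width of the profile in bp (default 250).
#' @param flank Range of |position| defining the normalization flank
#'   (default `c(200, 250)`).
#' @return Named list per group: `profile` (named numeric over relative
#'   positions), `n_insertions`, `flagged` (TRUE when the group had no
#'   usable insertions).
#' @export
footprint_profile <- function(fragments, motif_sites, nucleus_groups,
                              window = 250, flank = c(200, 250)) {
  centers <- floor((motif_sites$start + motif_sites$end) / 2)
  flip <- if (!is.null(motif_sites$strand)) motif_sites$strand == "-"
  else rep(FALSE, length(centers))
  positions <- seq.int(-window, window)
  lapply(nucleus_groups, function(members) {
    pos <- fragments$start[fragments$barcode %in% members]
    counts <- numeric(length(positions))
    for (si in seq_along(centers)) {
      rel <- pos - centers[[si]]
      if (flip[[si]]) rel <- -rel
      rel <- rel[abs(rel) <= window]
      if (length(rel))
        counts <- counts + tabulate(rel + window + 1L,
                                    nbins = length(positions))
    }
    in_flank <- abs(positions) >= flank[[1L]] & abs(positions) <= flank[[2L]]
    denom <- mean(counts[in_flank])
    if (sum(counts) == 0 || denom == 0)
      return(list(profile = stats::setNames(rep(NA_real_, length(positions)),
                                            positions),
                  n_insertions = sum(counts), flagged = TRUE))
    list(profile = stats::setNames(counts / denom, positions),
         n_insertions = sum(counts), flagged = FALSE)
  })
}
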