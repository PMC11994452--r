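# Independent oracles used to validate the fast implementations.

# Wilcoxon AUC by explicit pair counting: wins + half-ties over n1*n2 pairs.
auc_bruteforce <- function(x_in, x_out) {
  wins <- 0
  for (a in x_in) for (b in x_out)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(x_in) * length(x_out))
}

# Textbook Benjamini-Hochberg step-up: q_(i) = min_{j>=i} p_(j) * m / j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# All-pairs interval overlap under half-open semantics.
overlap_allpairs_oracle <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
      hits[[length(hits) + 1L]] <- data.frame(
        query = i, subject = j,
        overlap = min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
    }
  }
  if (!length(hits))
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  out <- do.call(rbind, hits)
  out[order(out$query, out$subject), , drop = FALSE]
}

# Naive triple-loop topological overlap.
tom_oracle <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (L + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

random_interval_set <- function(n, n_chrom = 2, max_pos = 100) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(10, n, replace = TRUE)
  afcellsig::interval_set(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start, end = start + width)
}

# Small multiome config for unit tests (not the acceptance-scale default).
tiny_config <- function(seed = 1L, ...) {
  afcellsig::sim_config(seed = seed, n_donors_af = 2, n_donors_sr = 2,
                        nuclei_per_donor = 120, n_genes = 400,
                        n_peaks = 200, n_motifs = 10, peaks_per_motif = 12,
                        markers_per_celltype = 10, sex_n_genes = 10,
                        n_private_degs = 10, bulk_n_per_group = 15, ...)
}
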