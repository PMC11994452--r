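#' Simulation configuration with planted ground truth parameters
#'
#' Defines the synthetic study: a left-atrial-appendage multiome cohort
#' (3 AF + 4 SR donors by default, mirroring a small paired snRNA/snATAC
#' study), two bulk RNA-seq cohorts sharing a planted AF program, a driver
#' transcription-factor motif whose peaks gain accessibility in AF
#' cardiomyocytes, one overlapping antisense gene pair emulating a
#' strandedness artifact, and Tn5 insertion positions with a protected
#' footprint at the driver motif.
#'
#' Counts are negative binomial with mean `mu` and variance
#' `mu + dispersion * mu^2`; per-observation library sizes are log-normal.
#' Effect sizes are multiplicative on the mean (log2 scale in the fields).
#'
#' @param seed Mandatory integer seed; every generator derives its RNG
#'   stream from it.
#' @param n_donors_af,n_donors_sr Donors per condition in the multiome arm.
#' @param n_celltypes Number of cell types (6-12; first is always `CM`).
#' @param nuclei_per_donor Nuclei simulated per donor.
#' @param n_genes,n_peaks,n_motifs Feature-space sizes.
#' @param markers_per_celltype Planted marker genes per cell type.
#' @param marker_log2fc Cell-type uplift of marker genes (log2).
#' @param n_planted_up,n_planted_down Size of the planted CM AF program.
#' @param af_log2fc AF-by-CM shift of the planted program genes (log2).
#' @param peaks_per_motif Peaks assigned to each motif.
#' @param driver_motif_effect Multiplicative accessibility gain of driver
#'   motif peaks in AF cardiomyocyte nuclei (1 = null).
#' @param driver_cm_effect Multiplicative accessibility gain of driver motif
#'   peaks in all cardiomyocyte nuclei (cell-type specificity of the motif).
#' @param nb_dispersion Negative-binomial dispersion `alpha`.
#' @param libsize_sdlog Log-normal sd of per-observation size factors.
#' @param bulk_n_per_group Samples per condition per bulk cohort.
#' @param bulk_lfc_range Magnitude range for planted bulk log2 fold changes;
#'   `c(0, 0)` yields a null bulk simulation.
#' @param n_private_degs Cohort-private planted DEGs per cohort.
#' @param sex_n_genes,sex_log2fc Genes carrying an additive (log-scale) sex
#'   covariate effect in the bulk cohorts, and its size.
#' @param frag_rate_per_bp Background Tn5 insertion rate per nucleus per bp.
#' @param frag_cm_flank,frag_af_cm_flank Flank insertion-rate multipliers at
#'   driver motif sites for SR and AF cardiomyocyte nuclei (others are 1).
#' @param footprint_core Half-width (bp) of the protected core; insertions
#'   inside it are removed. Set `frag_cm_flank = frag_af_cm_flank = 1` and
#'   `footprint_core = 0` for a uniform null.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_donors_af = 3, n_donors_sr = 4,
                       n_celltypes = 8, nuclei_per_donor = 300,
                       n_genes = 500, markers_per_celltype = 20,
                       marker_log2fc = 2,
                       n_planted_up = 30, n_planted_down = 30,
                       af_log2fc = 1,
                       n_peaks = 800, n_motifs = 30, peaks_per_motif = 25,
                       driver_motif_effect = 2, driver_cm_effect = 3,
                       nb_dispersion = 0.2, libsize_sdlog = 0.3,
                       bulk_n_per_group = 40, bulk_lfc_range = c(0.8, 1.5),
                       n_private_degs = 20,
                       sex_n_genes = 20, sex_log2fc = 1,
                       frag_rate_per_bp = 5e-4,
                       frag_cm_flank = 3, frag_af_cm_flank = 6,
                       footprint_core = 10) {
  if (missing(seed)) stopf("`seed` is mandatory in sim_config()")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  with(cfg, {
    if (n_celltypes < 2) stopf("need at least 2 cell types")
    if (n_planted_up + n_planted_down > n_genes)
      stopf("planted AF program larger than the gene universe")
    if (bulk_n_per_group < 2)
      stopf("need >= 2 samples per condition per cohort")
    if (any(c(n_donors_af, n_donors_sr, nuclei_per_donor, n_genes, n_peaks,
              n_motifs, peaks_per_motif, markers_per_celltype) <= 0))
      stopf("all size parameters must be positive")
    if (!all(is.finite(c(marker_log2fc, af_log2fc, driver_motif_effect,
                         driver_cm_effect, bulk_lfc_range))))
      stopf("effect sizes must be finite")
  })
  needed <- n_celltypes * markers_per_celltype + n_planted_up +
    n_planted_down + n_motifs + sex_n_genes + 2 + 2 * n_private_degs
  if (needed > n_genes)
    stopf("gene universe too small for the planted structure (%d needed)",
          needed)
  cfg$chrom <- "chrS"
  cfg$chrom_len <- as.integer(n_peaks * 250 + 10000)
  class(cfg) <- "sim_config"
  cfg
}

celltype_names <- function(n) {
  base <- c("CM", "FB", "EC", "Pericyte", "Myeloid", "Endocardial",
            "Adipocyte", "SMC", "Neuronal", "Lymphoid", "Mesothelial",
            "Mast")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("CT", seq_len(n - length(base))))
}

# Deterministic partition of the gene universe into planted roles.
plant_genes <- function(cfg) {
  ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  cts <- celltype_names(cfg$n_celltypes)
  i <- 0L
  take <- function(k) {
    sel <- ids[(i + 1L):(i + k)]
    i <<- i + k
    sel
  }
  markers <- stats::setNames(
    lapply(cts, function(ct) take(cfg$markers_per_celltype)), cts)
  af_up <- take(cfg$n_planted_up)
  af_down <- take(cfg$n_planted_down)
  tf_genes <- stats::setNames(take(cfg$n_motifs),
                              sprintf("M%02d", seq_len(cfg$n_motifs)))
  sex_genes <- take(cfg$sex_n_genes)
  antisense <- stats::setNames(take(2L), c("gene_plus", "gene_minus"))
  private1 <- take(cfg$n_private_degs)
  private2 <- take(cfg$n_private_degs)
  list(gene_ids = ids, celltypes = cts, marker_map = markers,
       af_up = af_up, af_down = af_down, tf_genes = tf_genes,
       sex_genes = sex_genes, antisense_pair = antisense,
       private1 = private1, private2 = private2)
}

rnbinom_mat <- function(mu, dispersion, dim, dimnames) {
  counts <- if (dispersion <= 1e-12) stats::rpois(length(mu), lambda = mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  matrix(counts, nrow = dim[1L], ncol = dim[2L], dimnames = dimnames)
}

#' Generate a synthetic multiome dataset with planted ground truth
#'
#' Simulates nucleus-by-gene and nucleus-by-peak count matrices for several
#' donors per condition. Marker genes receive a cell-type-specific mean
#' uplift; the planted AF program genes are cardiomyocyte-enriched and
#' shifted up (`af_up`) or down (`af_down`) in AF cardiomyocyte nuclei only.
#' Driver-motif peaks gain accessibility in all CMs
#' (`driver_cm_effect`) and additionally in AF CMs (`driver_motif_effect`).
#' The transcription factor gene paired with the driver motif is itself a CM
#' marker upregulated in AF CMs, so that motif activity and TF expression
#' carry concordant signal. Peak GC content is drawn Beta(5, 5) and
#' recorded. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return list with elements `rna` and `atac` (sparse nucleus-by-feature
#'   counts), `nuclei` (nucleus metadata), `peaks` (interval set with `gc`
#'   column), `motifs` (named list motif id -> peak ids) and `truth`.
#' @export
generate_multiome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  plan <- plant_genes(cfg)
  with_seed(cfg$seed + 1L, {
    cts <- plan$celltypes
    ct_prob <- c(0.25, 0.23, rep(0.52 / (cfg$n_celltypes - 2),
                                 cfg$n_celltypes - 2))[seq_along(cts)]
    ct_prob <- ct_prob / sum(ct_prob)
    donors <- c(sprintf("AF%d", seq_len(cfg$n_donors_af)),
                sprintf("SR%d", seq_len(cfg$n_donors_sr)))
    cond <- rep(c("AF", "SR"), c(cfg$n_donors_af, cfg$n_donors_sr))
    n_nuc <- length(donors) * cfg$nuclei_per_donor
    nuc <- nucleus_table(
      nucleus_id = sprintf("N%05d", seq_len(n_nuc)),
      donor_id = rep(donors, each = cfg$nuclei_per_donor),
      condition = rep(cond, each = cfg$nuclei_per_donor),
      cell_type = sample(cts, n_nuc, replace = TRUE, prob = ct_prob))

    base_mean <- stats::rlnorm(cfg$n_genes, meanlog = log(0.5), sdlog = 1)
    names(base_mean) <- plan$gene_ids
    sf <- stats::rlnorm(n_nuc, 0, cfg$libsize_sdlog)
    mu <- outer(sf, base_mean)
    is_af <- nuc$condition == "AF"
    is_cm <- nuc$cell_type == "CM"
    for (ct in cts)
      mu[nuc$cell_type == ct, plan$marker_map[[ct]]] <-
        mu[nuc$cell_type == ct, plan$marker_map[[ct]]] * 2^cfg$marker_log2fc
    cm_program <- c(plan$af_up, plan$af_down, unname(plan$tf_genes[1L]))
    mu[is_cm, cm_program] <- mu[is_cm, cm_program] * 2^cfg$marker_log2fc
    mu[is_af & is_cm, plan$af_up] <-
      mu[is_af & is_cm, plan$af_up] * 2^cfg$af_log2fc
    mu[is_af & is_cm, plan$af_down] <-
      mu[is_af & is_cm, plan$af_down] * 2^-cfg$af_log2fc
    driver_tf_gene <- unname(plan$tf_genes[1L])
    mu[is_af & is_cm, driver_tf_gene] <-
      mu[is_af & is_cm, driver_tf_gene] * 2^cfg$af_log2fc
    rna <- rnbinom_mat(mu, cfg$nb_dispersion, dim(mu),
                       list(nuc$nucleus_id, plan$gene_ids))

    peak_ids <- sprintf("P%04d", seq_len(cfg$n_peaks))
    gc <- stats::rbeta(cfg$n_peaks, 5, 5)
    starts <- as.integer((seq_len(cfg$n_peaks) - 1L) * 250L + 5000L)
    peaks <- interval_set(rep(cfg$chrom, cfg$n_peaks), starts, starts + 200L,
                          label = peak_ids)
    peaks$gc <- gc
    motif_ids <- names(plan$tf_genes)
    driver_motif <- motif_ids[[1L]]
    driver_peaks <- sample(peak_ids, cfg$peaks_per_motif)
    other_pool <- setdiff(peak_ids, driver_peaks)
    motifs <- c(stats::setNames(list(driver_peaks), driver_motif),
                stats::setNames(lapply(motif_ids[-1L], function(m)
                  sample(other_pool, cfg$peaks_per_motif)), motif_ids[-1L]))

    peak_mean <- stats::rlnorm(cfg$n_peaks, meanlog = log(0.3), sdlog = 0.5)
    names(peak_mean) <- peak_ids
    sf_atac <- stats::rlnorm(n_nuc, 0, cfg$libsize_sdlog)
    mu_p <- outer(sf_atac, peak_mean)
    mu_p[is_cm, driver_peaks] <- mu_p[is_cm, driver_peaks] *
      cfg$driver_cm_effect
    mu_p[is_af & is_cm, driver_peaks] <- mu_p[is_af & is_cm, driver_peaks] *
      cfg$driver_motif_effect
    atac <- rnbinom_mat(mu_p, cfg$nb_dispersion, dim(mu_p),
                        list(nuc$nucleus_id, peak_ids))

    truth <- list(marker_map = plan$marker_map, af_up = plan$af_up,
                  af_down = plan$af_down, driver_motif_id = driver_motif,
                  driver_tf_gene = driver_tf_gene, tf_genes = plan$tf_genes,
                  antisense_pair = plan$antisense_pair,
                  driver_peaks = driver_peaks)
    list(rna = as_sparse(rna), atac = as_sparse(atac), nuclei = nuc,
         peaks = peaks, motifs = motifs, truth = truth)
  })
}

#' Generate two synthetic bulk RNA-seq cohorts
#'
#' Both cohorts share the planted AF program genes as concordant DEGs (the
#' per-cohort log2 fold change magnitudes are drawn independently from
#' `bulk_lfc_range`); each cohort additionally carries private DEGs to
#' exercise the concordance filter. A binary sex covariate shifts a disjoint
#' gene set. The antisense pair overlaps on opposite strands: only
#' `gene_plus` is truly differential, and the returned "unstranded" variant
#' of cohort 2 reports the pair's summed counts for both genes, emulating
#' quantification without strand information.
#'
#' @param cfg A [sim_config()].
#' @return list with `cohort1`, `cohort2` (each `counts` samples-by-genes
#'   and `samples` metadata), `cohort2_unstranded` (counts matrix), `truth`
#'   (incl. `bulk_deg_map` of per-cohort log2 fold changes).
#' @export
generate_bulk_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  plan <- plant_genes(cfg)
  with_seed(cfg$seed + 2L, {
    draw_lfc <- function(n) stats::runif(n, cfg$bulk_lfc_range[1L],
                                         cfg$bulk_lfc_range[2L])
    lfc1 <- lfc2 <- stats::setNames(numeric(cfg$n_genes), plan$gene_ids)
    lfc1[plan$af_up] <- draw_lfc(cfg$n_planted_up)
    lfc2[plan$af_up] <- draw_lfc(cfg$n_planted_up)
    lfc1[plan$af_down] <- -draw_lfc(cfg$n_planted_down)
    lfc2[plan$af_down] <- -draw_lfc(cfg$n_planted_down)
    gp <- plan$antisense_pair[["gene_plus"]]
    lfc1[gp] <- draw_lfc(1L); lfc2[gp] <- draw_lfc(1L)
    lfc1[plan$private1] <- draw_lfc(cfg$n_private_degs) *
      sample(c(-1, 1), cfg$n_private_degs, replace = TRUE)
    lfc2[plan$private2] <- draw_lfc(cfg$n_private_degs) *
      sample(c(-1, 1), cfg$n_private_degs, replace = TRUE)
    sex_lfc <- stats::setNames(numeric(cfg$n_genes), plan$gene_ids)
    sex_lfc[plan$sex_genes] <- cfg$sex_log2fc

    base_mean <- stats::rlnorm(cfg$n_genes, meanlog = log(20), sdlog = 1)
    names(base_mean) <- plan$gene_ids

    sim_cohort <- function(prefix, lfc) {
      n <- 2L * cfg$bulk_n_per_group
      samples <- data.frame(
        sample_id = sprintf("%s_S%02d", prefix, seq_len(n)),
        condition = rep(c("AF", "SR"), each = cfg$bulk_n_per_group),
        sex = sample(c(0L, 1L), n, replace = TRUE),
        stringsAsFactors = FALSE)
      sf <- stats::rlnorm(n, 0, cfg$libsize_sdlog)
      mu <- outer(sf, base_mean) *
        2^(outer(as.numeric(samples$condition == "AF"), lfc)) *
        2^(outer(as.numeric(samples$sex), sex_lfc))
      counts <- rnbinom_mat(mu, cfg$nb_dispersion, dim(mu),
                            list(samples$sample_id, plan$gene_ids))
      list(counts = counts, samples = samples)
    }
    c1 <- sim_cohort("C1", lfc1)
    c2 <- sim_cohort("C2", lfc2)
    gm <- plan$antisense_pair[["gene_minus"]]
    unstranded <- c2$counts
    pair_sum <- c2$counts[, gp] + c2$counts[, gm]
    unstranded[, gp] <- pair_sum
    unstranded[, gm] <- pair_sum

    shared <- c(plan$af_up, plan$af_down)
    truth <- list(
      bulk_deg_map = data.frame(gene_id = plan$gene_ids, lfc1 = lfc1,
                                lfc2 = lfc2, stringsAsFactors = FALSE,
                                row.names = NULL),
      shared_degs = shared, private1 = plan$private1,
      private2 = plan$private2, sex_genes = plan$sex_genes,
      antisense_pair = plan$antisense_pair,
      af_up = plan$af_up, af_down = plan$af_down)
    list(cohort1 = c1, cohort2 = c2, cohort2_unstranded = unstranded,
         truth = truth)
  })
}

#' Generate Tn5 insertion positions with a protected motif footprint
#'
#' Each nucleus receives uniform background insertions along the synthetic
#' chromosome. Around each driver-motif site, cardiomyocyte nuclei get
#' additional flanking insertions (rate multiplier `frag_cm_flank` for SR,
#' `frag_af_cm_flank` for AF), while all insertions falling in the
#' `footprint_core` bp around the site center are removed (the protein-bound
#' footprint). Windows extending past the chromosome start are clipped with
#' a warning.
#'
#' @param cfg A [sim_config()].
#' @param motif_sites Interval set of motif sites (centers are midpoints).
#' @param nuclei Nucleus metadata table; condition and cell type control the
#'   flank multiplier. May have zero rows (empty output).
#' @return data.frame with columns `chrom`, `start`, `end`, `barcode`; each
#'   row is one 1-bp insertion event.
#' @export
generate_fragments <- function(cfg, motif_sites, nuclei) {
  stopifnot(inherits(cfg, "sim_config"))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), barcode = character(),
                      stringsAsFactors = FALSE)
  if (nrow(nuclei) == 0) return(empty)
  with_seed(cfg$seed + 3L, {
    centers <- as.integer(floor((motif_sites$start + motif_sites$end) / 2))
    window <- 250L
    if (any(centers - window < 0)) {
      warnf("footprint window extends past chromosome start; clipped")
    }
    n_nuc <- nrow(nuclei)
    # background, uniform along the chromosome
    n_bg <- stats::rpois(n_nuc, cfg$frag_rate_per_bp * cfg$chrom_len)
    pos <- floor(stats::runif(sum(n_bg), 0, cfg$chrom_len))
    bc <- rep(nuclei$nucleus_id, n_bg)
    # flank enrichment for CM nuclei at driver sites
    mult <- ifelse(nuclei$cell_type == "CM",
                   ifelse(nuclei$condition == "AF", cfg$frag_af_cm_flank,
                          cfg$frag_cm_flank), 1)
    # bound-TF shoulders: extra insertions concentrate within ~100 bp of
    # the site so the distal (200-250 bp) normalization flank stays flat
    shoulder <- 100L
    extra_rate <- cfg$frag_rate_per_bp * (mult - 1) *
      2 * (shoulder - cfg$footprint_core) * length(centers)
    n_extra <- stats::rpois(n_nuc, pmax(extra_rate, 0))
    if (sum(n_extra) > 0) {
      site <- centers[sample.int(length(centers), sum(n_extra),
                                 replace = TRUE)]
      side <- sample(c(-1L, 1L), sum(n_extra), replace = TRUE)
      off <- floor(stats::runif(sum(n_extra), cfg$footprint_core, shoulder))
      pos <- c(pos, site + side * off)
      bc <- c(bc, rep(nuclei$nucleus_id, n_extra))
    }
    keep <- pos >= 0 & pos < cfg$chrom_len
    pos <- pos[keep]; bc <- bc[keep]
    # protected core: drop every insertion within the footprint
    if (cfg$footprint_core > 0 && length(centers)) {
      in_core <- rep(FALSE, length(pos))
      for (cpos in centers)
        in_core <- in_core | abs(pos - cpos) <= cfg$footprint_core
      pos <- pos[!in_core]; bc <- bc[!in_core]
    }
    o <- order(pos, bc)
    data.frame(chrom = cfg$chrom, start = as.integer(pos[o]),
               end = as.integer(pos[o]) + 1L, barcode = bc[o],
               stringsAsFactors = FALSE)
  })
}

#' Generate a planted-block coexpression design
#'
#' Gaussian expression with `length(block_sizes)` planted gene modules:
#' each block gene is `sqrt(rho) * factor + sqrt(1 - rho) * noise` for a
#' shared per-block latent factor, giving within-block correlation `rho`;
#' noise genes are independent. Optionally two latent factors can be
#' correlated to exercise module merging.
#'
#' @param n_samples Number of samples (default 100).
#' @param block_sizes Integer vector of module sizes (default 3 x 60).
#' @param n_noise Number of unassigned noise genes (default 100).
#' @param block_cor Within-block correlation `rho` (default 0.7).
#' @param factor_cor Correlation between consecutive latent factors
#'   (default 0: independent modules).
#' @param seed RNG seed.
#' @return list with `expr` (samples-by-genes matrix) and `truth` (integer
#'   module label per gene, 0 for noise).
#' @export
generate_module_design <- function(n_samples = 100,
                                   block_sizes = c(60, 60, 60),
                                   n_noise = 100, block_cor = 0.7,
                                   factor_cor = 0, seed = 1L) {
  with_seed(seed, {
    n_blocks <- length(block_sizes)
    f <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
    if (factor_cor != 0 && n_blocks > 1) {
      for (b in 2:n_blocks)
        f[, b] <- factor_cor * f[, b - 1L] +
          sqrt(1 - factor_cor^2) * f[, b]
    }
    n_genes <- sum(block_sizes) + n_noise
    labels <- c(rep(seq_len(n_blocks), block_sizes), rep(0L, n_noise))
    expr <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
    for (b in seq_len(n_blocks)) {
      cols <- which(labels == b)
      expr[, cols] <- sqrt(block_cor) * f[, b] +
        sqrt(1 - block_cor) * expr[, cols]
    }
    dimnames(expr) <- list(sprintf("S%03d", seq_len(n_samples)),
                           sprintf("G%04d", seq_len(n_genes)))
    list(expr = expr, truth = stats::setNames(labels, colnames(expr)))
  })
}
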