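test_that("generators are deterministic given the seed", {
  cfg <- tiny_config(seed = 9L)
  a <- generate_multiome(cfg)
  b <- generate_multiome(cfg)
  expect_identical(as.matrix(a$rna), as.matrix(b$rna))
  expect_identical(as.matrix(a$atac), as.matrix(b$atac))
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$truth, b$truth)
  ba <- generate_bulk_cohorts(cfg)
  bb <- generate_bulk_cohorts(cfg)
  expect_identical(ba$cohort1$counts, bb$cohort1$counts)
  sites <- a$peaks[1:5, ]
  expect_identical(generate_fragments(cfg, sites, a$nuclei),
                   generate_fragments(cfg, sites, a$nuclei))
  # a different seed changes values but not shapes
  c2 <- generate_multiome(tiny_config(seed = 10L))
  expect_equal(dim(c2$rna), dim(a$rna))
  expect_false(identical(as.matrix(c2$rna), as.matrix(a$rna)))
})

test_that("planted markers are the most expressed in their cell type", {
  for (seed in 1:5) {
    mo <- generate_multiome(tiny_config(seed = seed))
    norm <- log_normalize(mo$rna)
    cts <- unique(mo$nuclei$cell_type)
    ct_means <- t(vapply(cts, function(ct)
      Matrix::colMeans(norm[mo$nuclei$cell_type == ct, , drop = FALSE]),
      numeric(ncol(norm))))
    for (ct in names(mo$truth$marker_map)) {
      for (g in mo$truth$marker_map[[ct]]) {
        expect_gt(ct_means[ct, g], max(ct_means[rownames(ct_means) != ct, g]))
      }
    }
  }
})

test_that("null driver effect leaves AF and SR CM accessibility equal", {
  cfg <- sim_config(seed = 3L, driver_motif_effect = 1)
  mo <- generate_multiome(cfg)
  cm <- mo$nuclei$cell_type == "CM"
  af <- mo$nuclei$condition == "AF"
  dp <- mo$truth$driver_peaks
  tot <- Matrix::rowSums(mo$atac)
  mean_acc <- Matrix::rowMeans(mo$atac[, dp, drop = FALSE]) / tot
  pv <- t.test(mean_acc[cm & af], mean_acc[cm & !af])$p.value
  expect_gt(pv, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(seed = 1, n_planted_up = 300, n_planted_down = 300,
                          n_genes = 500), "larger than the gene universe")
  expect_error(sim_config(seed = 1, bulk_n_per_group = 1), ">= 2 samples")
  expect_error(sim_config(), "mandatory")
})

test_that("unstranded variant reports the antisense pair sum per sample", {
  bulk <- generate_bulk_cohorts(tiny_config(seed = 4L))
  gp <- bulk$truth$antisense_pair[["gene_plus"]]
  gm <- bulk$truth$antisense_pair[["gene_minus"]]
  s <- bulk$cohort2$counts[, gp] + bulk$cohort2$counts[, gm]
  expect_equal(bulk$cohort2_unstranded[, gp], s)
  expect_equal(bulk$cohort2_unstranded[, gm], s)
  # everything else untouched
  others <- setdiff(colnames(bulk$cohort2$counts), c(gp, gm))
  expect_identical(bulk$cohort2_unstranded[, others],
                   bulk$cohort2$counts[, others])
})

test_that("null bulk simulation yields few concordant DEGs", {
  # lfc range pinned to zero: any concordant DEG is a false positive
  n_hits <- vapply(1:10, function(seed) {
    cfg <- tiny_config(seed = seed, bulk_lfc_range = c(0, 0))
    bulk <- generate_bulk_cohorts(cfg)
    de1 <- nb_glm_de(bulk$cohort1$counts, bulk$cohort1$samples,
                     covariates = "sex")
    de2 <- nb_glm_de(bulk$cohort2$counts, bulk$cohort2$samples,
                     covariates = "sex")
    nrow(concordant_degs(de1, de2))
  }, numeric(1))
  expect_lt(mean(n_hits), 0.05 * 400)
})

test_that("fragments: zero nuclei give an empty table; positions in range", {
  cfg <- tiny_config(seed = 5L)
  mo <- generate_multiome(cfg)
  empty <- generate_fragments(cfg, mo$peaks[1:3, ], mo$nuclei[0, ])
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("chrom", "start", "end", "barcode"))
  fr <- generate_fragments(cfg, mo$peaks[1:3, ], mo$nuclei[1:50, ])
  expect_true(all(fr$start >= 0 & fr$end <= cfg$chrom_len))
  expect_equal(fr$end, fr$start + 1L)
})

test_that("AF CM nuclei have more insertions near driver sites than SR CM", {
  hits <- vapply(1:5, function(seed) {
    cfg <- tiny_config(seed = seed)
    mo <- generate_multiome(cfg)
    sites <- mo$peaks[mo$peaks$label %in% mo$truth$driver_peaks, ]
    fr <- generate_fragments(cfg, sites, mo$nuclei)
    centers <- floor((sites$start + sites$end) / 2)
    near <- rep(FALSE, nrow(fr))
    for (cp in centers) near <- near | abs(fr$start - cp) <= 250
    tab <- table(factor(fr$barcode[near], levels = mo$nuclei$nucleus_id))
    per_nuc <- as.numeric(tab)
    cm <- mo$nuclei$cell_type == "CM"
    af <- mo$nuclei$condition == "AF"
    mean(per_nuc[cm & af]) > mean(per_nuc[cm & !af])
  }, logical(1))
  expect_true(all(hits))
})
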