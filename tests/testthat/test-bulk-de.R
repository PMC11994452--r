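test_that("size factors match the median-of-ratios hand computation", {
  m <- matrix(c(10, 20, 5, 10, 8, 16), nrow = 2,
              dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  # s2 = 2 * s1 elementwise -> factors (1/sqrt(2), sqrt(2))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> factors (1, 1)
  m2 <- rbind(s1 = c(3, 7, 1), s2 = c(3, 7, 1))
  expect_equal(unname(size_factors(m2)), c(1, 1))
  # a gene zero in one sample is excluded; factors as if it were dropped
  m3 <- cbind(m, g4 = c(0, 100))
  expect_equal(size_factors(m3), size_factors(m))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("in the dispersion->0 limit the Wald fit matches the closed-form
           Poisson rate ratio", {
  # Poisson GLM with offsets on a two-group design has the closed-form
  # MLE mu_g = sum(y in g) / sum(sf in g); the NB fit converges to it
  set.seed(5)
  n <- 10
  counts <- matrix(rpois(2 * n * 20, lambda = 40), ncol = 20)
  counts[, 1] <- c(rpois(n, 30), rpois(n, 90))
  rownames(counts) <- paste0("s", seq_len(2 * n))
  colnames(counts) <- paste0("g", 1:20)
  st <- data.frame(sample_id = rownames(counts),
                   condition = rep(c("SR", "AF"), each = n))
  de <- nb_glm_de(counts, st, dispersion = 1e-12)
  sf <- size_factors(counts)
  af <- st$condition == "AF"
  expected <- log2((colSums(counts[af, ]) / sum(sf[af])) /
                     (colSums(counts[!af, ]) / sum(sf[!af])))
  expect_equal(de$log2fc, unname(expected), tolerance = 1e-6)
})

test_that("NB GLM errors on confounded designs and flags all-zero genes", {
  counts <- matrix(rpois(8 * 5, 20), nrow = 8,
                   dimnames = list(paste0("s", 1:8), paste0("g", 1:5)))
  counts[, 5] <- 0
  st <- data.frame(sample_id = rownames(counts),
                   condition = rep(c("SR", "AF"), each = 4),
                   batch = rep(c(0, 1), each = 4))
  expect_error(nb_glm_de(counts, st, covariates = "batch"), "collinear")
  de <- nb_glm_de(counts, st)
  expect_true(is.na(de$log2fc[de$gene_id == "g5"]))
  expect_true(is.na(de$fdr[de$gene_id == "g5"]))
  # all-zero gene excluded from the BH denominator
  expect_equal(de$fdr[1:4], bh_fdr(de$p[1:4]))
})

test_that("pseudobulk honours the detection threshold and conserves counts", {
  cfg <- tiny_config(seed = 6L)
  mo <- generate_multiome(cfg)
  pb <- pseudobulk_aggregate(mo$rna, mo$nuclei, min_frac = 0.05)
  ct <- "CM"
  sel <- mo$nuclei$cell_type == ct
  detected <- Matrix::colMeans(mo$rna[sel, , drop = FALSE] > 0)
  expect_setequal(colnames(pb[[ct]]$counts), names(detected)[detected > 0.05])
  # column sums of pseudobulk rows equal summed raw counts of the nuclei
  kept <- colnames(pb[[ct]]$counts)
  expect_equal(colSums(pb[[ct]]$counts),
               Matrix::colSums(mo$rna[sel, kept, drop = FALSE]))
  # single-nucleus group: pseudobulk row equals that nucleus
  one <- mo$nuclei[1, , drop = FALSE]
  pb1 <- pseudobulk_aggregate(mo$rna[1, , drop = FALSE], one, min_frac = 0)
  row1 <- pb1[[one$cell_type]]$counts
  kept1 <- colnames(row1)
  expect_equal(unname(row1[1, ]),
               unname(as.matrix(mo$rna)[1, kept1]))
})

test_that("concordance rules: both-significant, same sign, symmetric", {
  de <- function(g, l, f) data.frame(gene_id = g, log2fc = l, fdr = f)
  d1 <- de(c("a", "b", "c"), c(1, 1, 1), c(0.01, 0.01, 0.01))
  d2 <- de(c("a", "b", "c"), c(0.5, -1, 1), c(0.02, 0.01, 0.2))
  cc <- concordant_degs(d1, d2)
  expect_equal(cc$gene_id, "a")     # b discordant, c not significant twice
  expect_equal(cc$sign, 1)
  cc_swap <- concordant_degs(d2, d1)
  expect_equal(cc_swap$gene_id, cc$gene_id)
  # "either" reading keeps c (significant in d1, same sign in d2)
  cc_e <- concordant_degs(d1, d2, mode = "either")
  expect_setequal(cc_e$gene_id, c("a", "c"))
  expect_warning(concordant_degs(d1, de("zz", 1, 0.01)), "no genes shared")
})

test_that("DEG cell-type assignment respects direction and keeps misses", {
  bulk_cc <- data.frame(gene_id = c("g1", "g2"), sign = c(1, 1))
  ct_de <- list(
    FB = data.frame(gene_id = c("g1", "g2"), log2fc = c(2, -2),
                    fdr = c(0.01, 0.01)),
    CM = data.frame(gene_id = c("g1", "g2"), log2fc = c(1, 1),
                    fdr = c(0.5, 0.6)))
  asn <- assign_degs_to_celltypes(bulk_cc, ct_de)
  expect_equal(asn$cell_types[[1]], "FB")   # up in FB, concordant
  expect_equal(asn$n_celltypes[2], 0L)      # g2: discordant FB, ns CM
  expect_equal(asn$gene_id, c("g1", "g2"))  # misses retained
})

test_that("strand artifact flags only unstranded-specific significance", {
  des <- data.frame(gene_id = c("p", "m"), fdr = c(0.001, 0.9),
                    log2fc = c(1, 0))
  deu <- data.frame(gene_id = c("p", "m"), fdr = c(0.002, 0.01),
                    log2fc = c(1, 1))
  pairs <- data.frame(gene_plus = "p", gene_minus = "m")
  flags <- strand_artifact_check(des, deu, pairs)
  expect_false(flags$flagged[flags$gene_id == "p"])  # significant both ways
  expect_true(flags$flagged[flags$gene_id == "m"])
  expect_equal(flags$partner[flags$gene_id == "m"], "p")
  # absent pair -> warning, skipped; empty pair list -> empty output
  expect_warning(out <- strand_artifact_check(des, deu,
    data.frame(gene_plus = "x", gene_minus = "y")), "skipped")
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(strand_artifact_check(des, deu, pairs[0, ])), 0L)
})

test_that("fixed-dispersion fits agree with the reference Poisson GLM, with
           covariates included", {
  set.seed(8)
  counts <- matrix(rpois(12 * 6, 30), nrow = 12,
                   dimnames = list(paste0("s", 1:12), paste0("g", 1:6)))
  st <- data.frame(sample_id = rownames(counts),
                   condition = rep(c("SR", "AF"), each = 6),
                   sex = rep(c(0, 1), 6))
  de <- nb_glm_de(counts, st, covariates = "sex", dispersion = 1e-12)
  pois <- vapply(seq_len(ncol(counts)), function(j) {
    fit <- glm(counts[, j] ~ factor(st$condition, c("SR", "AF")) + st$sex,
               family = poisson,
               offset = log(size_factors(counts)))
    coef(fit)[2] / log(2)
  }, numeric(1))
  expect_equal(de$log2fc, unname(pois), tolerance = 1e-6)
})
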