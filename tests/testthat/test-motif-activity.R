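test_that("peak bias bins are equal-frequency and degenerate cases collapse", {
  set.seed(31)
  counts <- matrix(rpois(50 * 200, 2), 50, 200,
                   dimnames = list(paste0("c", 1:50), paste0("p", 1:200)))
  gc <- runif(200)
  bias <- peak_bias(counts, gc, n_bins = 10)
  expect_true(all(abs(table(bias$gc_bin) - 20) <= 1))
  # the accessibility covariate is discrete (count means), so its quantile
  # bins need only be monotone in the covariate and cover all peaks
  o <- order(bias$log_mean_access)
  expect_true(all(diff(bias$access_bin[o]) >= 0))
  expect_false(anyNA(bias$joint_bin))
  # identical counts and GC -> everything in one joint bin
  counts1 <- matrix(3, 20, 30, dimnames = list(paste0("c", 1:20),
                                               paste0("p", 1:30)))
  bias1 <- peak_bias(counts1, rep(0.5, 30))
  expect_equal(length(unique(bias1$joint_bin)), 1L)
  expect_warning(peak_bias(counts1[, 1:5], rep(0.5, 5), n_bins = 10),
                 "collapsing")
})

test_that("background sampling stays in-bin, is seeded, spans all peaks when
           the grid is degenerate", {
  set.seed(32)
  counts <- matrix(rpois(40 * 100, 2), 40, 100,
                   dimnames = list(paste0("c", 1:40), paste0("p", 1:100)))
  bias <- peak_bias(counts, runif(100), n_bins = 5)
  bg <- sample_background_peaks(bias, n_bg = 20, seed = 7)
  for (i in seq_len(nrow(bias)))
    expect_true(all(bias$joint_bin[bg[i, ]] == bias$joint_bin[i]))
  expect_identical(bg, sample_background_peaks(bias, n_bg = 20, seed = 7))
  # single-bin case draws from everywhere
  counts1 <- matrix(3, 20, 30, dimnames = list(paste0("c", 1:20),
                                               paste0("p", 1:30)))
  bias1 <- peak_bias(counts1, rep(0.5, 30))
  bg1 <- sample_background_peaks(bias1, n_bg = 500, seed = 8)
  expect_gt(length(unique(as.vector(bg1))), 25)
})

test_that("the all-peaks motif has exactly zero raw deviation", {
  set.seed(33)
  counts <- matrix(rpois(30 * 50, 3), 30, 50,
                   dimnames = list(paste0("c", 1:30), paste0("p", 1:50)))
  counts[1, ] <- counts[1, ] + 1  # no all-zero observation
  bias <- peak_bias(counts, runif(50), n_bins = 3)
  bg <- sample_background_peaks(bias, n_bg = 10, seed = 2)
  dev <- motif_deviations(counts, list(all = colnames(counts)), bg)
  expect_equal(unname(dev$raw[, "all"]), rep(0, 30))
})

test_that("z-scores are invariant to a global doubling of counts", {
  cfg <- tiny_config(seed = 34L)
  mo <- generate_multiome(cfg)
  bias <- peak_bias(mo$atac, mo$peaks$gc)
  bg <- sample_background_peaks(bias, seed = 5)
  z1 <- motif_deviations(mo$atac, mo$motifs, bg)$z
  bias2 <- peak_bias(mo$atac * 2, mo$peaks$gc)
  bg2 <- sample_background_peaks(bias2, seed = 5)
  z2 <- motif_deviations(mo$atac * 2, mo$motifs, bg2)$z
  expect_identical(is.na(z1), is.na(z2))
  expect_equal(mean(abs(z1 - z2), na.rm = TRUE), 0, tolerance = 0.05)
  expect_error(motif_deviations(mo$atac, list(m = character()), bg),
               "no peaks")
})

test_that("footprint profiles: uniform null is flat, protected core is zero", {
  set.seed(35)
  sites <- interval_set("chrS", c(1000L, 3000L), c(1200L, 3200L))
  centers <- floor((sites$start + sites$end) / 2)
  n_frag <- 60000
  frag <- data.frame(chrom = "chrS",
                     start = sample.int(5000, n_frag, replace = TRUE) - 1L,
                     barcode = "n1", stringsAsFactors = FALSE)
  frag$end <- frag$start + 1L
  fp <- footprint_profile(frag, sites, list(g = "n1"))$g
  expect_false(fp$flagged)
  expect_equal(mean(fp$profile), 1, tolerance = 0.1)
  expect_true(all(abs(fp$profile - 1) < 0.6))
  # carve out the core -> profile 0 in the core, ~1 in flanks
  core <- rep(FALSE, n_frag)
  for (cp in centers) core <- core | abs(frag$start - cp) <= 10
  fp2 <- footprint_profile(frag[!core, ], sites, list(g = "n1"))$g
  pos <- as.integer(names(fp2$profile))
  expect_equal(unname(fp2$profile[abs(pos) <= 10]), rep(0, 21))
  expect_equal(mean(fp2$profile[abs(pos) >= 200]), 1, tolerance = 0.1)
  # group without insertions is flagged
  fp3 <- footprint_profile(frag[0, ], sites, list(g = "n1"))$g
  expect_true(fp3$flagged)
})

test_that("minus-strand sites are orientation-flipped", {
  sites <- interval_set("chrS", 1000L, 1100L, strand = "-")
  center <- 1050L
  # symmetric flank anchors the normalization; the asymmetric cluster sits
  # right of the center and must appear at negative positions after the flip
  anchors <- center + c(-(250:200), 200:250)
  cluster <- 1060:1070
  frag <- data.frame(chrom = "chrS", start = c(anchors, cluster),
                     barcode = "n1", stringsAsFactors = FALSE)
  frag$end <- frag$start + 1L
  fp <- footprint_profile(frag, sites, list(g = "n1"))$g
  pos <- as.integer(names(fp$profile))
  expect_true(all(fp$profile[pos >= 10 & pos <= 20] == 0))
  expect_gt(sum(fp$profile[pos <= -10 & pos >= -20]), 0)
})
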