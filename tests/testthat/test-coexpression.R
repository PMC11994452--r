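test_that("gene prefilter applies strict thresholds", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   base_mean = c(2, 0.5, 1, 2),
                   log2fc = c(0.1, 1, 1, 0.05),
                   p = c(0.01, 1e-6, 1e-6, 0.01))
  kept <- prefilter_genes(de)
  expect_equal(kept, "a")  # b fails base_mean, c boundary base_mean, d lfc
})

test_that("covariate residualization removes batch means exactly", {
  set.seed(61)
  batch <- rep(c(0, 1), each = 10)
  y_exact <- 5 + 2 * batch
  x <- cbind(exact = y_exact,
             ortho = rnorm(20),
             mixed = rnorm(20) + 3 * batch)
  # make 'ortho' numerically orthogonal to the centered covariate
  x[, "ortho"] <- resid(lm(x[, "ortho"] ~ batch)) + 1
  out <- residualize_covariates(x, cbind(batch = batch))
  expect_lt(var(out[, "exact"]), 1e-20)
  expect_equal(mean(out[, "exact"]), mean(y_exact))  # grand mean preserved
  expect_equal(out[, "ortho"], x[, "ortho"], tolerance = 1e-12)
  expect_lt(abs(mean(out[batch == 1, "mixed"]) -
                  mean(out[batch == 0, "mixed"])), 1e-10)
  expect_error(residualize_covariates(x, cbind(b1 = batch, b2 = batch * 2)),
               "collinear")
})

test_that("batch shifts on many genes vanish after residualization", {
  set.seed(62)
  n <- 40; g <- 50
  batch <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * g), n, g)
  x[, 1:25] <- x[, 1:25] + 2 * batch
  out <- residualize_covariates(x, cbind(batch))
  diffs <- abs(colMeans(out[batch == 1, ]) - colMeans(out[batch == 0, ]))
  expect_lt(max(diffs), 1e-10)
})

test_that("signed adjacency closed forms", {
  n <- 50
  set.seed(63)
  base <- rnorm(n)
  x <- cbind(a = base, b = base * 2 + 1, c = -base, d = rnorm(n))
  adj <- signed_adjacency(x, power = 9)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 0)
  expect_equal(diag(adj), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(adj, tol = 1e-12))
  # cor = 0 -> 0.5^9 (check against an exactly orthogonalized pair)
  d_orth <- resid(lm(x[, "d"] ~ base))
  adj2 <- signed_adjacency(cbind(a = base, d = d_orth), power = 9)
  expect_equal(adj2["a", "d"], 0.5^9, tolerance = 1e-12)
  expect_error(signed_adjacency(cbind(a = base, k = rep(1, n))), "constant")
})

test_that("TOM matches hand computation and the triple-loop oracle", {
  # two genes with a = 1 and no other neighbours: TOM = (0+1)/(1+1-1) = 1
  a <- diag(2); a[1, 2] <- a[2, 1] <- 1
  expect_equal(topological_overlap(a)[1, 2], 1)
  # zero off-diagonal adjacency stays zero
  expect_equal(topological_overlap(diag(3))[1, 2], 0)
  set.seed(64)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    r <- matrix(runif(n * n), n)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- topological_overlap(a)
    expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom, tol = 1e-12))
  }
})

test_that("module detection recovers planted blocks and drops small ones", {
  sim <- generate_module_design(seed = 65)
  tom <- topological_overlap(signed_adjacency(sim$expr, power = 9))
  mods <- detect_modules(tom, sim$expr)
  expect_gte(mclust::adjustedRandIndex(mods$labels, sim$truth), 0.9)
  expect_true(all(table(mods$labels[mods$labels != 0]) >= 50))
  sim40 <- generate_module_design(block_sizes = c(40, 40, 40), seed = 66)
  m40 <- detect_modules(topological_overlap(
    signed_adjacency(sim40$expr, 9)), sim40$expr)
  expect_true(all(m40$labels == 0))
  expect_error(detect_modules(tom, sim$expr, cut_height = 1.2), "cut_height")
})

test_that("strongly correlated blocks merge into one module", {
  sim <- generate_module_design(block_sizes = c(60, 60), n_noise = 100,
                                factor_cor = 0.95, seed = 67)
  mods <- detect_modules(topological_overlap(
    signed_adjacency(sim$expr, 9)), sim$expr)
  expect_equal(length(setdiff(unique(mods$labels), 0L)), 1L)
})

test_that("eigengenes summarize modules with a stable orientation", {
  set.seed(68)
  profile <- rnorm(30)
  x <- sapply(1:5, function(i) profile)
  colnames(x) <- paste0("g", 1:5)
  labels <- setNames(rep(1L, 5), colnames(x))
  me <- module_eigengene(x, labels)
  # identical genes: eigengene is the shared standardized profile
  expect_equal(abs(cor(me[, "ME1"], profile)), 1, tolerance = 1e-10)
  # orientation: positively correlated with the module mean
  expect_gt(cor(me[, "ME1"], rowMeans(scale(x))), 0)
  # deterministic across runs
  expect_identical(me, module_eigengene(x, labels))
  # single-gene module falls back to the standardized profile
  one <- module_eigengene(x[, 1, drop = FALSE], setNames(1L, "g1"))
  expect_equal(unname(one[, 1]), as.numeric(scale(x[, 1])))
})
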