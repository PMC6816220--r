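test_that("CPM matches its definition on hand-computable cases", {
  m <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
  x <- count_matrix(m, c("miRNA", "miRNA"))
  expect_equal(unname(cpm(x)$E[, 1]), c(250000, 750000))

  # all-equal counts, logged -> all values equal
  me <- matrix(7, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  v <- cpm(count_matrix(me, rep("miRNA", 3)), log = TRUE)$E
  expect_true(diff(range(v)) == 0)

  # logged zero count against the stated offset formula
  mz <- matrix(c(0, 999996, 4), 3, 1, dimnames = list(c("z", "big", "c"), "s1"))
  v <- cpm(count_matrix(mz, rep("miRNA", 3)), log = TRUE, prior_count = 0.5)$E
  expect_equal(v["z", 1], log2(0.5 / (1e6 + 1) * 1e6))

  expect_error(cpm(x, prior_count = -1), "prior_count")
})

test_that("unlogged CPM columns sum to 1e6 over non-calibrator features", {
  x <- toy_counts()
  v <- cpm(x)$E
  expect_equal(unname(colSums(v[!x$is_calibrator, ])), rep(1e6, 3))
})

test_that("calibrator size factors follow geometric-mean arithmetic", {
  # identical calibrator profiles -> all factors 1
  m <- rbind(f1 = c(10, 20), `cal` = c(50, 50))
  colnames(m) <- c("s1", "s2")
  x <- count_matrix(m, c("miRNA", "other"), c(FALSE, TRUE))
  expect_equal(unname(calibrator_size_factors(x)), c(1, 1))

  # one sample with calibrators uniformly doubled -> factor 2 vs others
  m2 <- rbind(f1 = c(1, 1, 1), c1 = c(10, 20, 10), c2 = c(40, 80, 40))
  colnames(m2) <- paste0("s", 1:3)
  x2 <- count_matrix(m2, c("miRNA", "other", "other"), c(FALSE, TRUE, TRUE))
  sf <- calibrator_size_factors(x2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  # single calibrator, counts (4, 1) -> factors (2, 0.5)
  m3 <- rbind(f1 = c(5, 5), c1 = c(4, 1))
  colnames(m3) <- c("s1", "s2")
  x3 <- count_matrix(m3, c("miRNA", "other"), c(FALSE, TRUE))
  expect_equal(unname(calibrator_size_factors(x3)), c(2, 0.5))

  # zero calibrator counts are an error naming the sample
  m4 <- rbind(f1 = c(5, 5), c1 = c(4, 0))
  colnames(m4) <- c("s1", "s2")
  x4 <- count_matrix(m4, c("miRNA", "other"), c(FALSE, TRUE))
  expect_error(calibrator_size_factors(x4), "s2")
})

test_that("calibrator factors are invariant under a global rescaling", {
  x <- toy_counts()
  sf1 <- calibrator_size_factors(x)
  x2 <- x
  x2$counts[x2$is_calibrator, ] <- x2$counts[x2$is_calibrator, ] * 3
  expect_equal(calibrator_size_factors(x2), sf1)
})

test_that("expression filter is inclusive at both thresholds", {
  # feature at exactly min_cpm in exactly half the samples is kept
  m <- rbind(lowhalf = c(1, 1, 0, 0), high = c(999999, 999999, 1e6, 1e6))
  colnames(m) <- paste0("s", 1:4)
  x <- count_matrix(m, c("miRNA", "miRNA"))
  kept <- filter_expressed(x, min_cpm = 1, min_fraction = 0.5)
  expect_true("lowhalf" %in% rownames(kept$counts))  # cpm == 1 in 2/4 samples

  # all-zero feature is dropped; min_fraction = 0 keeps everything
  m2 <- rbind(zero = c(0, 0), ok = c(10, 10))
  colnames(m2) <- c("s1", "s2")
  x2 <- count_matrix(m2, c("miRNA", "miRNA"))
  expect_false("zero" %in% rownames(filter_expressed(x2)$counts))
  expect_identical(nrow(filter_expressed(x2, min_fraction = 0)$counts), 2L)
  expect_error(filter_expressed(x2, min_fraction = 1.2), "min_fraction")
})

test_that("expression filter is idempotent and monotone in min_cpm", {
  sim <- simulate_cohort(small_config(seed = 4))
  f1 <- filter_expressed(sim$counts, min_cpm = 1)
  f1b <- filter_expressed(f1, min_cpm = 1)
  expect_identical(rownames(f1$counts), rownames(f1b$counts))
  f5 <- filter_expressed(sim$counts, min_cpm = 5)
  expect_true(all(rownames(f5$counts) %in% rownames(f1$counts)))
})

test_that("class composition sums to 1 and reflects pure compositions", {
  m <- rbind(a = c(10, 5), b = c(10, 5))
  colnames(m) <- c("s1", "s2")
  x <- count_matrix(m, c("miRNA", "miRNA"))
  comp <- class_composition(x)
  expect_equal(unname(comp[, "miRNA"]), c(1, 1))

  x2 <- count_matrix(m, c("miRNA", "tRNA"))
  comp2 <- class_composition(x2)
  expect_equal(unname(comp2[, "miRNA"]), c(0.5, 0.5))
  expect_equal(unname(rowSums(comp2)), c(1, 1))
})

test_that("quantile normalization equalizes column distributions", {
  e <- expr_matrix(matrix(c(1, 2, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2"))))
  q <- quantile_normalize(e)$E
  expect_equal(unname(q), matrix(c(2, 3, 2, 3), 2))

  # identical columns unchanged; all columns share means afterwards
  e2 <- expr_matrix(matrix(c(5, 1, 3, 5, 1, 3), 3, 2,
                           dimnames = list(letters[1:3], c("s1", "s2"))))
  expect_equal(quantile_normalize(e2)$E, e2$E)

  set.seed(8)
  e3 <- expr_matrix(matrix(rnorm(60), 12, 5,
                           dimnames = list(paste0("f", 1:12), paste0("s", 1:5))))
  q3 <- quantile_normalize(e3)$E
  expect_equal(diff(range(colMeans(q3))), 0, tolerance = 1e-12)
  expect_equal(apply(q3, 2, sort), matrix(rep(sort(q3[, 1]), 5), ncol = 5,
                                          dimnames = list(NULL, colnames(q3))))
  # agrees with the established implementation
  skip_if_not_installed("limma")
  expect_equal(unname(q3), unname(limma::normalizeQuantiles(e3$E)))

  expect_warning(quantile_normalize(expr_matrix(e3$E[, 1, drop = FALSE])), "single sample")
})

test_that("quantile normalization gives ties the mean of their reference values", {
  e <- expr_matrix(matrix(c(1, 1, 5, 2, 4, 6), 3, 2,
                          dimnames = list(letters[1:3], c("s1", "s2"))))
  ref <- rowMeans(cbind(sort(e$E[, 1]), sort(e$E[, 2])))
  q <- quantile_normalize(e)$E
  expect_equal(unname(q[1:2, 1]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(q[3, 1]), unname(ref[3]))
})

test_that("PCA reconstructs the centered matrix and separates groups", {
  set.seed(5)
  E <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(paste0("f", 1:20), paste0("s", 1:8)))
  x <- expr_matrix(E, scale = "log2_intensity")
  p <- pca_expr(x, n_components = 8)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(unname(recon), unname(t(E - rowMeans(E))), tolerance = 1e-8)
  expect_true(sum(p$variance_explained) <= 1 + 1e-12)
  expect_error(pca_expr(x, n_components = 25), "n_components")

  # duplicate samples give zero variance beyond the first components
  E2 <- E[, c(1, 1, 2, 2)]
  colnames(E2) <- paste0("d", 1:4)
  p2 <- pca_expr(expr_matrix(E2, scale = "log2_intensity"), n_components = 4)
  expect_lt(sum(p2$variance_explained[-1]), 1e-12 + p2$variance_explained[1])

  # two composition groups separate on PC1 (tissue- vs serum-like)
  sim <- simulate_cohort(small_config(seed = 9))
  keep <- sim$metadata$compartment %in% c("tumor", "serum")
  ids <- sim$metadata$sample_id[keep]
  lx <- cpm(sim$counts[, ids], log = TRUE)
  pp <- pca_expr(expr_matrix(lx$E[!sim$counts$is_calibrator, ], scale = "log2_cpm"),
                 n_components = 2)
  grp <- sim$metadata$compartment[match(rownames(pp$scores), sim$metadata$sample_id)]
  pc1 <- pp$scores[, 1]
  expect_gt(abs(mean(pc1[grp == "tumor"]) - mean(pc1[grp == "serum"])),
            sd(pc1[grp == "tumor"]) + sd(pc1[grp == "serum"]))
})
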