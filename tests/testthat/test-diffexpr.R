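test_that("precision weights follow the mean-variance trend", {
  fx <- nb_fixture(seed = 7)
  v <- voom_weights(fx$counts, fx$design)
  expect_identical(dim(v$weights), dim(v$E))
  expect_true(all(v$weights > 0))

  # NB counts: weights increase with mean at the low-abundance end
  mu <- rowMeans(fx$counts$counts)
  low <- mu < stats::quantile(mu, 0.4)
  expect_gt(cor(mu[low], rowMeans(v$weights)[low], method = "spearman"), 0)

  # identical count rows get identical weight rows
  cts <- fx$counts$counts
  cts["f002", ] <- cts["f001", ]
  x2 <- count_matrix(cts, rep("miRNA", nrow(cts)))
  v2 <- voom_weights(x2, fx$design)
  expect_equal(unname(v2$weights["f001", ]), unname(v2$weights["f002", ]))

  expect_error(voom_weights(fx$counts, cbind(1, fx$group, fx$group)), "full rank")
})

test_that("near-homoscedastic data yields a nearly flat weight surface", {
  withr::with_seed(13, {
    n <- 20
    # equal library sizes and lognormal 'counts' whose log-scale variance is
    # constant: the fitted trend should be close to flat
    y <- matrix(round(exp(rnorm(200 * n, 8, 0.3))), 200,
                dimnames = list(paste0("f", 1:200), paste0("s", 1:n)))
    x <- count_matrix(y, rep("miRNA", 200))
    v <- voom_weights(x, cbind(1, rep(0:1, each = n / 2)))
    expect_lt(diff(range(v$weights)) / mean(v$weights), 0.2)
  })
})

test_that("the engine reproduces the reference empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  fx <- nb_fixture(seed = 42)
  v <- voom_weights(fx$counts, fx$design)
  fit <- fit_and_moderate(v, fx$design, coef = "group")

  vo <- limma::voom(fx$counts$counts, fx$design)
  fo <- limma::eBayes(limma::lmFit(vo, fx$design))
  expect_equal(unname(v$weights), unname(vo$weights), tolerance = 1e-10)
  expect_equal(fit$d0, fo$df.prior, tolerance = 1e-8)
  expect_equal(fit$s0_2, fo$s2.prior, tolerance = 1e-8)
  expect_equal(fit$table$t, unname(fo$t[, 2]), tolerance = 1e-10)
  expect_equal(fit$table$p, unname(fo$p.value[, 2]), tolerance = 1e-10)
  expect_equal(fit$table$logFC, unname(fo$coefficients[, 2]), tolerance = 1e-10)
})

test_that("imposed prior df limits recover the classical t-tests exactly", {
  withr::with_seed(9, {
    n <- 10
    y <- matrix(rnorm(50 * n), 50, dimnames = list(paste0("f", 1:50), paste0("s", 1:n)))
    grp <- rep(0:1, each = 5)
    design <- cbind(`(Intercept)` = 1, group = grp)
    x <- expr_matrix(y, scale = "log2_intensity")

    # d0 = 0: per-feature two-sample equal-variance t
    f0 <- fit_and_moderate(x, design, coef = "group", d0 = 0)
    tref <- apply(y, 1, function(r) stats::t.test(r[grp == 1], r[grp == 0],
                                                  var.equal = TRUE)$statistic)
    expect_equal(f0$table$t, unname(tref), tolerance = 1e-10)

    # d0 = Inf: pooled-variance t across features
    finf <- fit_and_moderate(x, design, coef = "group", d0 = Inf)
    s2 <- apply(y, 1, function(r) {
      fit <- stats::lm.fit(design, r); sum(fit$residuals^2) / (n - 2)
    })
    s2pool <- mean(s2)   # equal df per feature
    d <- apply(y, 1, function(r) mean(r[grp == 1]) - mean(r[grp == 0]))
    tpool <- d / sqrt(s2pool * (1 / 5 + 1 / 5))
    expect_equal(finf$table$t, unname(tpool), tolerance = 1e-10)
    expect_equal(unique(round(finf$s2_post, 14)), round(s2pool, 14))
  })
})

test_that("moderated t is monotone in the coefficient at fixed variance", {
  withr::with_seed(3, {
    n <- 8
    grp <- rep(0:1, each = 4)
    design <- cbind(1, grp)
    base <- rnorm(n, 0, 1)
    shifts <- c(0.1, 0.5, 1, 2)
    y <- do.call(rbind, lapply(shifts, function(s) base + s * grp))
    dimnames(y) <- list(paste0("f", seq_along(shifts)), paste0("s", 1:n))
    fit <- fit_and_moderate(expr_matrix(y, scale = "log2_intensity"), design, coef = 2)
    expect_true(all(diff(fit$table$t) > 0))   # same residuals, growing effect
  })
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  withr::with_seed(2, {
    for (i in 1:5) {
      p <- runif(97)^2
      expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
      perm <- sample(length(p))
      expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])  # order equivariance
    }
  })
})

test_that("run_contrast finds planted effects and respects label symmetry", {
  cfg <- small_config(
    seed = 61, n_patients_discovery = 15L, n_controls = 0L,
    planted_effects = list(planted_effect("miR-0001", "tumor_vs_normal", 2),
                           planted_effect("miR-0002", "tumor_vs_normal", -2)))
  sim <- simulate_cohort(cfg)
  de <- run_contrast(sim$counts, sim$metadata, "tumor_vs_normal", paired = TRUE)
  expect_true(de$significant[de$feature == "miR-0001"])
  expect_gt(de$logFC[de$feature == "miR-0001"], 0)
  expect_true(de$significant[de$feature == "miR-0002"])
  expect_lt(de$logFC[de$feature == "miR-0002"], 0)
  expect_identical(unname(attr(de, "n_group")), c(15L, 15L))
  expect_true(all(de$adj_p >= de$p))
  expect_false(any(sim$counts$is_calibrator[de$feature]))

  # swapping groups negates logFC, keeps p
  md2 <- sim$metadata
  md2$compartment[md2$compartment == "tumor"] <- "x"
  md2$compartment[md2$compartment == "normal"] <- "tumor"
  md2$compartment[md2$compartment == "x"] <- "normal"
  de2 <- run_contrast(sim$counts, md2, "tumor_vs_normal", paired = TRUE)
  shared <- intersect(de$feature, de2$feature)
  expect_equal(de$logFC[match(shared, de$feature)],
               -de2$logFC[match(shared, de2$feature)], tolerance = 1e-10)
  expect_equal(de$p[match(shared, de$feature)],
               de2$p[match(shared, de2$feature)], tolerance = 1e-10)
})

test_that("covariate adjustment and pairing are wired into the design", {
  cfg <- small_config(seed = 71, n_patients_discovery = 12L, n_controls = 0L)
  sim <- simulate_cohort(cfg)
  de <- run_contrast(sim$counts, sim$metadata, "tumor_vs_normal",
                     adjust_for = "sample_age")
  expect_s3_class(de, "de_result")

  # group identical to a covariate -> confounded design error
  md <- sim$metadata
  md$fake <- as.numeric(md$compartment == "tumor")
  expect_error(run_contrast(sim$counts, md, "tumor_vs_normal",
                            adjust_for = "fake"), "confounded|full rank")

  # clinical contrast in a stated compartment
  de_hbv <- run_contrast(sim$counts, sim$metadata, "HBV",
                         compartments = "serum", adjust_for = "sample_age")
  expect_true(all(c("feature", "logFC", "adj_p") %in% names(de_hbv)))
  expect_error(run_contrast(sim$counts, sim$metadata, "HBV"), "compartment")
})
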