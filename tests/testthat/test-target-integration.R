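mk_expr <- function(m, scale = "log2_cpm") {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expr_matrix(m, scale = scale)
}

test_that("the upper-quartile expression filter interpolates and is strict", {
  m <- rbind(interp = c(8, 9, 10, 11),    # P75 = 10.25 > 10 -> kept
             at_cut = rep(10, 4),         # P75 = 10, not > 10 -> dropped
             high = rep(12, 4))
  e <- mk_expr(m)
  kept <- filter_mirna_expression(e)
  expect_setequal(kept, c("interp", "high"))
  expect_equal(unname(quantile(m["interp", ], 0.75)), 10.25)
  expect_error(filter_mirna_expression(mk_expr(m, "log2_intensity")), "log2_cpm")
})

test_that("the context-score filter is strictly below the cutoff", {
  tt <- data.frame(mirna_id = c("m1", "m2", "m3"), gene_id = c("g1", "g2", "g3"),
                   weighted_context_score = c(-0.41, -0.4, -0.39))
  out <- filter_context_score(tt)
  expect_identical(out$mirna_id, "m1")
  expect_identical(nrow(filter_context_score(tt[0, ])), 0L)
})

test_that("directional consistency keeps only strongly one-sided genes", {
  de <- data.frame(feature = paste0("m", 1:5), logFC = c(1, 2, 1.5, -1, -2))
  tt4 <- data.frame(mirna_id = paste0("m", 1:4), gene_id = "gA",
                    weighted_context_score = -0.5)
  # 3 up / 1 down = 0.75, not > 0.75 -> gene dropped
  expect_identical(nrow(filter_directional_consistency(tt4, de)), 0L)

  # all 4 up -> kept with all 4 pairs
  de_all_up <- data.frame(feature = paste0("m", 1:4), logFC = c(1, 2, 1.5, 1))
  out <- filter_directional_consistency(tt4, de_all_up)
  expect_identical(nrow(out), 4L)
  expect_true(all(out$mirna_direction == "up"))

  # 4 up / 1 down = 0.8 > 0.75 -> kept with the 4 up pairs only
  tt5 <- data.frame(mirna_id = paste0("m", 1:5), gene_id = "gB",
                    weighted_context_score = -0.5)
  de5 <- data.frame(feature = paste0("m", 1:5), logFC = c(1, 2, 1.5, 1, -2))
  out5 <- filter_directional_consistency(tt5, de5)
  expect_identical(nrow(out5), 4L)
  expect_setequal(out5$mirna_id, paste0("m", 1:4))

  # a miRNA without a DE direction is dropped with a warning
  tt_unknown <- rbind(tt5, data.frame(mirna_id = "m9", gene_id = "gB",
                                      weighted_context_score = -0.5))
  expect_warning(filter_directional_consistency(tt_unknown, de5), "unknown")
})

test_that("anticorrelation filter keeps r < 0 and drops degenerate pairs", {
  withr::with_seed(23, {
    n <- 30
    mir <- mk_expr(rbind(m1 = rnorm(n, 10), m2 = rnorm(n, 10)))
    g1 <- 2 * mir$E["m1", ] + 1          # positive affine transform: r = 1
    g2 <- -0.8 * mir$E["m2", ] + rnorm(n, 0, 0.1)
    g3 <- rep(5, n)                       # constant -> undefined r
    mrna <- mk_expr(rbind(g1 = g1, g2 = g2, g3 = g3), "log2_intensity")
    tt <- data.frame(mirna_id = c("m1", "m2", "m2"),
                     gene_id = c("g1", "g2", "g3"),
                     weighted_context_score = -0.5)
    out <- NULL
    expect_warning(out <- filter_anticorrelation(tt, mir, mrna), "constant")
    expect_identical(out$gene_id, "g2")
    expect_lt(out$correlation, -0.9)
    expect_error(filter_anticorrelation(tt, mk_expr(mir$E[, 1:2]), mrna), "shared")
  })
})

test_that("the cascade recovers planted repressed pairs among decoys", {
  cfg <- small_config(seed = 91, n_patients_discovery = 30L, n_controls = 0L,
                      n_genes = 400L, target_density = 0.02,
                      repression_slope = -1)
  sim <- simulate_cohort(cfg)
  md <- sim$metadata
  tum <- md$sample_id[md$compartment == "tumor"]
  lx <- cpm(sim$counts, log = TRUE)
  mir_rows <- names(sim$counts$feature_class)[sim$counts$feature_class == "miRNA"]
  mir_t <- expr_matrix(lx$E[mir_rows, tum], scale = "log2_cpm")
  # plant 20 pairs on 20 highly expressed miRNAs, all "significant up"
  hi <- names(sort(rowMeans(mir_t$E), decreasing = TRUE))[1:20]
  mm <- simulate_mrna(cfg, mir_t, setNames(rep(2, 20), hi), noise_sd = 0.15)
  de_sig <- data.frame(feature = rownames(mir_t$E),
                       logFC = ifelse(rownames(mir_t$E) %in% hi, 2,
                                      rep(c(1, -1), length.out = nrow(mir_t$E))),
                       adj_p = 0.01)
  res <- run_cascade(de_sig, mm$targets, mir_t, mm$expr,
                     expr_threshold = min(apply(mir_t$E[hi, ], 1, quantile, 0.75)) - 0.01)
  key <- function(d) paste(d$mirna_id, d$gene_id)
  recall <- mean(key(mm$truth) %in% key(res$retained_pairs))
  expect_gte(recall, 0.9)
  expect_true(all(res$retained_pairs$correlation < 0))
  expect_true(all(diff(res$attrition) <= 0))

  # row order of the target table does not matter
  perm <- sample(nrow(mm$targets))
  res2 <- run_cascade(de_sig, mm$targets[perm, ], mir_t, mm$expr,
                      expr_threshold = min(apply(mir_t$E[hi, ], 1, quantile, 0.75)) - 0.01)
  expect_setequal(key(res$retained_pairs), key(res2$retained_pairs))
})

test_that("with filters disabled the cascade reduces to the r < 0 rule", {
  withr::with_seed(29, {
    n <- 20
    mir <- mk_expr(matrix(rnorm(5 * n, 12), 5, n,
                          dimnames = list(paste0("m", 1:5), paste0("s", 1:n))))
    mrna <- mk_expr(matrix(rnorm(10 * n, 8), 10, n,
                           dimnames = list(paste0("g", 1:10), paste0("s", 1:n))),
                    "log2_intensity")
    tt <- expand.grid(mirna_id = paste0("m", 1:5), gene_id = paste0("g", 1:10),
                      stringsAsFactors = FALSE)
    tt$weighted_context_score <- runif(nrow(tt), -1, 0)
    de <- data.frame(feature = paste0("m", 1:5), logFC = 1, adj_p = 0.01)
    res <- run_cascade(de, tt, mir, mrna, expr_threshold = -Inf,
                       score_cutoff = 0, min_fraction = 0)
    r_all <- apply(tt, 1, function(row)
      cor(mir$E[row[["mirna_id"]], ], mrna$E[row[["gene_id"]], ]))
    expect_identical(nrow(res$retained_pairs), sum(r_all < 0))
    # null data: about half of the pairs survive the sign-only filter
    expect_gt(nrow(res$retained_pairs) / nrow(tt), 0.3)
    expect_lt(nrow(res$retained_pairs) / nrow(tt), 0.7)

    # empty DE table -> empty result
    empty <- run_cascade(de[0, ], tt, mir, mrna)
    expect_identical(nrow(empty$retained_pairs), 0L)
  })
})

test_that("enrichment p-values are exact hypergeometric tail probabilities", {
  universe <- paste0("g", 1:20)
  sets <- list(S = paste0("g", 1:5))
  # all 5 selected genes inside the 5-gene set: p = 1 / choose(20, 5)
  res <- enrich_gene_sets(paste0("g", 1:5), universe, sets, p_cutoff = 0.01)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, 1 / 15504, tolerance = 1e-12)
  expect_true(res$significant)

  # selection = universe -> no enrichment possible
  res2 <- enrich_gene_sets(universe, universe, sets)
  expect_equal(res2$p, 1)

  # empty gene list -> empty table; empty universe -> error
  expect_identical(nrow(enrich_gene_sets(character(0), universe, sets)), 0L)
  expect_error(enrich_gene_sets("g1", character(0), sets), "universe")
  expect_warning(enrich_gene_sets(c("g1", "zz"), universe, sets), "not in universe")
})
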