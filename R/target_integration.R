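# Four-filter miRNA -> target integration cascade: restrict predicted
# miRNA-gene pairs by (1) miRNA expression level, (2) predicted repression
# strength (weighted context score), (3) directional consistency of the
# miRNAs targeting each gene, (4) observed miRNA-mRNA anticorrelation; then
# test the surviving genes for gene-set over-representation.

#' Filter miRNAs by upper-quartile expression
#'
#' Keeps miRNAs whose per-sample expression has its `percentile`-th
#' percentile (linear interpolation between order statistics) strictly
#' above `threshold` log2 CPM.
#'
#' @param mirna_expr [expr_matrix()] on the log2_cpm scale.
#' @param percentile percentile in (0, 100), default 75.
#' @param threshold log2 CPM cut, default 10; strict (`>`).
#' @return Character vector of retained miRNA ids.
#' @export
filter_mirna_expression <- function(mirna_expr, percentile = 75, threshold = 10) {
  stopifnot(inherits(mirna_expr, "expr_matrix"))
  if (mirna_expr$scale != "log2_cpm")
    stop("miRNA expression must be on the log2_cpm scale, got: ", mirna_expr$scale)
  q <- apply(mirna_expr$E, 1L, quantile, probs = percentile / 100, type = 7,
             names = FALSE)
  rownames(mirna_expr$E)[q > threshold]
}

#' Filter target pairs by predicted repression strength
#'
#' Keeps pairs whose weighted context score is strictly below `cutoff`
#' (more negative = stronger predicted repression).
#'
#' @param targets target table (`mirna_id`, `gene_id`,
#'   `weighted_context_score`).
#' @param cutoff score cut, default -0.4; strict (`<`).
#' @return Filtered target table.
#' @export
filter_context_score <- function(targets, cutoff = -0.4) {
  targets[targets$weighted_context_score < cutoff, , drop = FALSE]
}

#' Filter genes by directional consistency of their targeting miRNAs
#'
#' For every gene, looks up the differential-expression direction of each
#' targeting miRNA and keeps the gene only if the fraction of its miRNAs
#' in the majority direction is strictly above `min_fraction`; the
#' retained pairs are restricted to the majority-direction miRNAs.  Pairs
#' whose miRNA has no direction in `de` (not tested) are dropped with a
#' warning.
#'
#' @param targets target table.
#' @param de DE table supplying directions via `sign(logFC)`; normally
#'   pre-restricted to significant miRNAs.
#' @param min_fraction majority fraction cut, default 0.75; strict (`>`).
#' @return Filtered target table with a `mirna_direction` column
#'   (`"up"`/`"down"`).
#' @export
filter_directional_consistency <- function(targets, de, min_fraction = 0.75) {
  if (min_fraction < 0 || min_fraction > 1) stop("min_fraction must be in [0, 1]")
  dir <- setNames(sign(de$logFC), de$feature)
  known <- targets$mirna_id %in% names(dir)
  if (any(!known)) {
    warning(sum(!known), " pair(s) dropped: miRNA direction unknown (",
            paste(head(unique(targets$mirna_id[!known]), 3L), collapse = ", "), ")")
    targets <- targets[known, , drop = FALSE]
  }
  d <- dir[targets$mirna_id]
  zero <- d == 0
  if (any(zero)) targets <- targets[!zero, , drop = FALSE]
  d <- d[!zero]
  if (!nrow(targets)) {
    targets$mirna_direction <- character(0)
    return(targets)
  }
  keep <- logical(nrow(targets))
  majority <- numeric(nrow(targets))
  for (g in unique(targets$gene_id)) {
    idx <- which(targets$gene_id == g)
    n_up <- sum(d[idx] > 0)
    frac <- max(n_up, length(idx) - n_up) / length(idx)
    maj <- if (n_up >= length(idx) - n_up) 1 else -1
    if (frac > min_fraction) {
      keep[idx] <- d[idx] == maj
      majority[idx] <- maj
    }
  }
  out <- targets[keep, , drop = FALSE]
  out$mirna_direction <- ifelse(d[keep] > 0, "up", "down")
  out
}

#' Filter target pairs by observed anticorrelation
#'
#' Correlates each pair's miRNA and gene expression over the samples the
#' two matrices share and keeps pairs with r < 0.  Pairs with a missing
#' miRNA/gene or a degenerate (constant) expression vector are dropped
#' with a warning.
#'
#' @param targets target table (optionally with `mirna_direction`).
#' @param mirna_expr,mrna_expr [expr_matrix()] objects sharing >= 3
#'   sample ids.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Target table with a `correlation` column, restricted to r < 0.
#' @export
filter_anticorrelation <- function(targets, mirna_expr, mrna_expr,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(mirna_expr, "expr_matrix"), inherits(mrna_expr, "expr_matrix"))
  shared <- intersect(colnames(mirna_expr$E), colnames(mrna_expr$E))
  if (length(shared) < 3L)
    stop("need >= 3 shared samples between miRNA and mRNA expression, got ",
         length(shared))
  xm <- mirna_expr$E[, shared, drop = FALSE]
  xg <- mrna_expr$E[, shared, drop = FALSE]
  present <- targets$mirna_id %in% rownames(xm) & targets$gene_id %in% rownames(xg)
  if (any(!present)) {
    warning(sum(!present), " pair(s) dropped: miRNA or gene missing from expression")
    targets <- targets[present, , drop = FALSE]
  }
  if (!nrow(targets)) {
    targets$correlation <- numeric(0)
    return(targets)
  }
  r <- vapply(seq_len(nrow(targets)), function(i) {
    u <- xm[targets$mirna_id[i], ]
    v <- xg[targets$gene_id[i], ]
    if (sd(u) == 0 || sd(v) == 0) NA_real_ else cor(u, v, method = method)
  }, numeric(1))
  degenerate <- is.na(r)
  if (any(degenerate))
    warning(sum(degenerate), " pair(s) dropped: undefined correlation (constant expression)")
  targets$correlation <- r
  targets[!degenerate & r < 0, , drop = FALSE]
}

#' Run the four-filter miRNA-target integration cascade
#'
#' Applies, in order: restriction of the target table to the miRNAs in
#' `de_mirna` (the significant set), the miRNA expression filter, the
#' context-score filter, the directional-consistency filter, and the
#' anticorrelation filter.  Records the number of pairs surviving each
#' stage.
#'
#' @param de_mirna DE table restricted to the significant miRNAs driving
#'   the analysis.
#' @param targets predicted target table.
#' @param mirna_expr log2-CPM miRNA expression ([expr_matrix()]).
#' @param mrna_expr log2 mRNA expression ([expr_matrix()]); correlation
#'   runs over the samples shared with `mirna_expr`.
#' @param percentile,expr_threshold miRNA expression filter parameters.
#' @param score_cutoff context-score cut (default -0.4).
#' @param min_fraction directional-consistency cut (default 0.75).
#' @param cor_method correlation type for the final filter.
#' @return List of class `cascade_result`: `retained_pairs` (data.frame
#'   with `mirna_id`, `gene_id`, `weighted_context_score`,
#'   `mirna_direction`, `correlation`), `retained_mirnas`,
#'   `retained_genes`, and `attrition` (named pair counts after each
#'   stage).
#' @export
run_cascade <- function(de_mirna, targets, mirna_expr, mrna_expr,
                        percentile = 75, expr_threshold = 10,
                        score_cutoff = -0.4, min_fraction = 0.75,
                        cor_method = "pearson") {
  attrition <- c(input = nrow(targets))
  tt <- targets[targets$mirna_id %in% de_mirna$feature, , drop = FALSE]
  attrition <- c(attrition, de_mirnas = nrow(tt))
  if (nrow(tt)) {
    keep_mirnas <- filter_mirna_expression(mirna_expr, percentile, expr_threshold)
    tt <- tt[tt$mirna_id %in% keep_mirnas, , drop = FALSE]
  }
  attrition <- c(attrition, expression = nrow(tt))
  tt <- filter_context_score(tt, score_cutoff)
  attrition <- c(attrition, context_score = nrow(tt))
  if (nrow(tt)) tt <- filter_directional_consistency(tt, de_mirna, min_fraction)
  attrition <- c(attrition, direction = nrow(tt))
  if (nrow(tt)) tt <- filter_anticorrelation(tt, mirna_expr, mrna_expr,
                                             method = cor_method)
  attrition <- c(attrition, anticorrelation = nrow(tt))
  if (is.null(tt$mirna_direction)) tt$mirna_direction <- character(0)
  if (is.null(tt$correlation)) tt$correlation <- numeric(0)
  rownames(tt) <- NULL
  structure(list(retained_pairs = tt,
                 retained_mirnas = unique(tt$mirna_id),
                 retained_genes = unique(tt$gene_id),
                 attrition = attrition),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("cascade_result:", length(x$retained_mirnas), "miRNAs,",
      length(x$retained_genes), "unique target genes\n  attrition:",
      paste(sprintf("%s=%d", names(x$attrition), x$attrition), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric test per gene set against a detected-gene
#' universe, with Benjamini-Hochberg adjustment across sets.  Query genes
#' outside the universe are dropped with a warning; set members are
#' intersected with the universe.
#'
#' @param genes character vector of selected genes.
#' @param universe character vector of all testable genes.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param p_cutoff adjusted-p threshold for the `significant` flag
#'   (default 0.01).
#' @return data.frame with one row per set: `set`, `set_size` (in
#'   universe), `overlap`, `expected`, `p`, `adj_p`, `significant`.
#' @export
enrich_gene_sets <- function(genes, universe, gene_sets, p_cutoff = 0.01) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  genes <- unique(genes)
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) not in universe dropped")
    genes <- intersect(genes, universe)
  }
  if (!length(genes) || !length(gene_sets))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p = numeric(0), adj_p = numeric(0),
                      significant = logical(0)))
  N <- length(universe)
  n <- length(genes)
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    K <- length(intersect(gene_sets[[nm]], universe))
    k <- length(intersect(gene_sets[[nm]], genes))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k,
               expected = n * K / N, p = p, stringsAsFactors = FALSE)
  }))
  res$adj_p <- bh_adjust(res$p)
  res$significant <- res$adj_p < p_cutoff
  res[order(res$p), ]
}
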