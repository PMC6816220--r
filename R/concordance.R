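# Cross-comparison set logic: which features behave consistently between two
# independent contrasts (e.g. tumor vs normal tissue and exosome vs serum),
# and how well a validation cohort reproduces discovery directions.

de_significant <- function(de, alpha) de$feature[!is.na(de$adj_p) & de$adj_p < alpha]

#' Sign concordance between two differential expression contrasts
#'
#' Computes the feature sets behind a two-contrast concordance analysis:
#' the union of significant features, those expressed in all supplied
#' sample types, those with identical nonzero logFC signs in both
#' contrasts, those significant in both, and the overlap of the last two.
#' A zero logFC carries no sign and is excluded from `same_sign`.
#'
#' @param de_a,de_b DE tables ([run_contrast()] layout: `feature`,
#'   `logFC`, `adj_p`).
#' @param expressed list of character vectors, each the expressed feature
#'   set of one sample type (e.g. from [filter_expressed()] per
#'   compartment); their intersection defines "expressed in all".
#' @param alpha significance threshold on `adj_p`, in (0, 1).
#' @return List of class `concordance_result` with `union_significant`,
#'   `expressed_in_all`, `same_sign`, `both_significant`,
#'   `both_significant_same_sign`, `logfc_pairs` (data.frame feature /
#'   logFC_A / logFC_B over features present in both tables), and
#'   `pearson_r` (over `both_significant` pairs; `NA` when fewer than 3).
#' @export
compare_contrasts <- function(de_a, de_b, expressed, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!length(intersect(de_a$feature, de_b$feature)))
    stop("the two DE tables share no features")
  sig_a <- de_significant(de_a, alpha)
  sig_b <- de_significant(de_b, alpha)
  union_sig <- union(sig_a, sig_b)
  expr_all <- Reduce(intersect, expressed)
  expressed_in_all <- intersect(union_sig, expr_all)
  shared <- intersect(de_a$feature, de_b$feature)
  lfc_a <- setNames(de_a$logFC, de_a$feature)[shared]
  lfc_b <- setNames(de_b$logFC, de_b$feature)[shared]
  same_sign_all <- shared[sign(lfc_a) == sign(lfc_b) & sign(lfc_a) != 0]
  same_sign <- intersect(expressed_in_all, same_sign_all)
  both_sig <- intersect(sig_a, sig_b)
  both_sig_same <- intersect(both_sig, same_sign_all)
  pairs <- data.frame(feature = shared, logFC_A = unname(lfc_a),
                      logFC_B = unname(lfc_b), stringsAsFactors = FALSE)
  r <- if (length(both_sig) >= 3L) {
    bp <- pairs[pairs$feature %in% both_sig, ]
    if (sd(bp$logFC_A) > 0 && sd(bp$logFC_B) > 0)
      cor(bp$logFC_A, bp$logFC_B) else NA_real_
  } else NA_real_
  structure(list(union_significant = union_sig,
                 expressed_in_all = expressed_in_all,
                 same_sign = same_sign,
                 both_significant = both_sig,
                 both_significant_same_sign = both_sig_same,
                 logfc_pairs = pairs,
                 pearson_r = r),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("concordance_result:\n",
      sprintf("  significant in either contrast: %d\n", length(x$union_significant)),
      sprintf("  ... expressed in all sample types: %d\n", length(x$expressed_in_all)),
      sprintf("  ... with identical logFC signs: %d\n", length(x$same_sign)),
      sprintf("  significant in both contrasts: %d (same sign: %d)\n",
              length(x$both_significant), length(x$both_significant_same_sign)),
      sprintf("  Pearson r over both-significant logFCs: %s\n",
              ifelse(is.na(x$pearson_r), "NA", format(x$pearson_r, digits = 3))),
      sep = "")
  invisible(x)
}

#' Directional validation of discovery hits in an independent cohort
#'
#' Evaluable features are those significant in the discovery table and
#' present (detected) in the validation table; features the validation
#' cohort did not detect are excluded from the denominator.  Consistency
#' means equal nonzero logFC sign.
#'
#' @param de_discovery,de_validation DE tables.
#' @param alpha significance threshold applied to the discovery table.
#' @return List with `n_evaluable`, `n_consistent`, `fraction` (`NA` when
#'   nothing is evaluable) and the evaluable feature/direction table.
#' @export
validate_directions <- function(de_discovery, de_validation, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  sig <- de_significant(de_discovery, alpha)
  evaluable <- intersect(sig, de_validation$feature)
  lfc_d <- setNames(de_discovery$logFC, de_discovery$feature)[evaluable]
  lfc_v <- setNames(de_validation$logFC, de_validation$feature)[evaluable]
  consistent <- sign(lfc_d) == sign(lfc_v) & sign(lfc_d) != 0
  list(n_evaluable = length(evaluable),
       n_consistent = sum(consistent),
       fraction = if (length(evaluable)) sum(consistent) / length(evaluable)
                  else NA_real_,
       table = data.frame(feature = evaluable,
                          logFC_discovery = unname(lfc_d),
                          logFC_validation = unname(lfc_v),
                          consistent = unname(consistent),
                          stringsAsFactors = FALSE))
}
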