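# Independent brute-force reference implementations of the concordance set
# logic (double loops, no set algebra), used by both the module tests and the
# acceptance checks.

brute_concordance <- function(de_a, de_b, expressed, alpha) {
  sig <- function(de) de$feature[de$adj_p < alpha]
  union_sig <- character(0)
  for (f in unique(c(de_a$feature, de_b$feature)))
    if (f %in% sig(de_a) || f %in% sig(de_b)) union_sig <- c(union_sig, f)
  expr_all <- character(0)
  for (f in union_sig) {
    in_all <- TRUE
    for (s in expressed) if (!f %in% s) in_all <- FALSE
    if (in_all) expr_all <- c(expr_all, f)
  }
  same <- character(0)
  for (f in expr_all) {
    ia <- match(f, de_a$feature); ib <- match(f, de_b$feature)
    if (!is.na(ia) && !is.na(ib)) {
      sa <- sign(de_a$logFC[ia]); sb <- sign(de_b$logFC[ib])
      if (sa == sb && sa != 0) same <- c(same, f)
    }
  }
  both <- intersect(sig(de_a), sig(de_b))
  both_same <- character(0)
  for (f in both) {
    ia <- match(f, de_a$feature); ib <- match(f, de_b$feature)
    sa <- sign(de_a$logFC[ia]); sb <- sign(de_b$logFC[ib])
    if (sa == sb && sa != 0) both_same <- c(both_same, f)
  }
  list(union_significant = union_sig, expressed_in_all = expr_all,
       same_sign = same, both_significant = both,
       both_significant_same_sign = both_same)
}

brute_validate <- function(de_d, de_v, alpha) {
  n_eval <- 0L; n_cons <- 0L
  for (i in seq_len(nrow(de_d))) {
    if (de_d$adj_p[i] < alpha && de_d$feature[i] %in% de_v$feature) {
      n_eval <- n_eval + 1L
      j <- match(de_d$feature[i], de_v$feature)
      if (sign(de_d$logFC[i]) == sign(de_v$logFC[j]) && sign(de_d$logFC[i]) != 0)
        n_cons <- n_cons + 1L
    }
  }
  list(n_evaluable = n_eval, n_consistent = n_cons,
       fraction = if (n_eval) n_cons / n_eval else NA_real_)
}

random_de <- function(features) {
  data.frame(feature = features,
             logFC = round(rnorm(length(features)), 2) *
               rbinom(length(features), 1, 0.9),  # some exact zeros
             adj_p = runif(length(features)),
             stringsAsFactors = FALSE)
}
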