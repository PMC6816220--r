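# Library size = column sum over non-calibrator features: spike-ins are added
# at fixed amounts and must not absorb biological signal.
lib_sizes <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  colSums(x$counts[!x$is_calibrator, , drop = FALSE])
}

#' Counts per million
#'
#' Scales each sample to reads per million, where the library size is the
#' column sum over non-calibrator features, optionally multiplied by
#' per-sample size factors (see [calibrator_size_factors()]).  On the log
#' scale the value is
#' `log2((count + prior_count) / (lib * sf + 2 * prior_count) * 1e6)`,
#' the offset convention of precision-weighted linear modelling of counts.
#'
#' @param x a [count_matrix()].
#' @param log return log2 CPM instead of CPM.
#' @param prior_count nonnegative offset used only when `log = TRUE`.
#' @param size_factors optional positive per-sample factors (named or in
#'   column order); the effective library size is `lib * size_factor`.
#' @return An [expr_matrix()] covering all features (calibrators included),
#'   scale `"cpm"` or `"log2_cpm"`.
#' @export
cpm <- function(x, log = FALSE, prior_count = 0.5, size_factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (prior_count < 0) stop("prior_count must be >= 0")
  lib <- lib_sizes(x)
  if (any(lib <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(x$counts)[lib <= 0], collapse = ", "))
  if (!is.null(size_factors)) {
    if (!is.null(names(size_factors)))
      size_factors <- size_factors[colnames(x$counts)]
    if (length(size_factors) != ncol(x$counts) || any(!is.finite(size_factors)) ||
        any(size_factors <= 0))
      stop("size_factors must be positive, one per sample")
    lib <- lib * size_factors
  }
  if (log) {
    v <- t(log2(t(x$counts + prior_count) / (lib + 2 * prior_count) * 1e6))
    expr_matrix(v, scale = "log2_cpm")
  } else {
    expr_matrix(t(t(x$counts) / lib * 1e6), scale = "cpm")
  }
}

#' Spike-in calibrator size factors
#'
#' Per-sample normalization factors from the calibrator features: the
#' geometric mean of a sample's calibrator counts, rescaled so that the
#' geometric mean of the factors across samples is 1.  A sample whose
#' calibrator counts contain zeros cannot be normalized this way and is an
#' error (no pseudocounting).
#'
#' @param x a [count_matrix()] with at least one calibrator feature.
#' @return Named positive numeric vector, one factor per sample, with
#'   geometric mean 1.
#' @export
calibrator_size_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  cal <- x$counts[x$is_calibrator, , drop = FALSE]
  if (nrow(cal) == 0L) stop("no calibrator features present")
  all_zero <- colSums(cal > 0) == 0L
  if (any(all_zero))
    stop("all calibrator counts are zero in sample(s): ",
         paste(colnames(cal)[all_zero], collapse = ", "))
  any_zero <- colSums(cal == 0) > 0L
  if (any(any_zero))
    stop("zero calibrator count(s) in sample(s): ",
         paste(colnames(cal)[any_zero], collapse = ", "),
         "; calibrator factors require all calibrators detected")
  gm <- exp(colMeans(log(cal)))
  gm / exp(mean(log(gm)))
}

#' Filter features by expression level
#'
#' Keeps features whose unlogged CPM is at least `min_cpm` in at least
#' `min_fraction` of the `within` samples ("at least" inclusive on both
#' thresholds).  Calibrator features are always kept: they carry
#' normalization information, not biology.
#'
#' @param x a [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction required fraction of samples (default 0.5).
#' @param within sample ids defining both the CPM computation and the
#'   fraction denominator; default all samples.
#' @param size_factors optional size factors passed to [cpm()].
#' @return The filtered [count_matrix()] (all samples retained).
#' @export
filter_expressed <- function(x, min_cpm = 1, min_fraction = 0.5, within = NULL,
                             size_factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (min_fraction < 0 || min_fraction > 1) stop("min_fraction must be in [0, 1]")
  within <- within %||% colnames(x$counts)
  if (length(within) == 0L) stop("'within' must name at least one sample")
  if (!all(within %in% colnames(x$counts)))
    stop("unknown sample(s) in 'within': ",
         paste(setdiff(within, colnames(x$counts)), collapse = ", "))
  sub <- x[, within]
  if (!is.null(size_factors) && !is.null(names(size_factors)))
    size_factors <- size_factors[within]
  v <- cpm(sub, log = FALSE, size_factors = size_factors)$E
  n_ok <- rowSums(v >= min_cpm)
  keep <- n_ok >= min_fraction * length(within) - 1e-9
  x[keep | x$is_calibrator, ]
}

#' Per-sample RNA-class read composition
#'
#' Fraction of each sample's non-calibrator reads attributed to each RNA
#' class, e.g. to compare tRNA depletion in exosomes against whole serum.
#'
#' @param x a [count_matrix()].
#' @return Matrix (samples x RNA classes) of fractions, each row summing
#'   to 1.
#' @export
class_composition <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- !x$is_calibrator
  cts <- x$counts[keep, , drop = FALSE]
  cls <- x$feature_class[keep]
  tot <- colSums(cts)
  if (any(tot <= 0))
    stop("no non-calibrator reads in sample(s): ",
         paste(colnames(cts)[tot <= 0], collapse = ", "))
  out <- sapply(RNA_CLASSES, function(k)
    colSums(cts[cls == k, , drop = FALSE]) / tot)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(colnames(cts), RNA_CLASSES))
  out
}

#' Quantile normalization across samples
#'
#' Forces every column onto a common reference distribution: the row-wise
#' mean of the per-column order statistics.  Ties within a column receive
#' the mean of their tied reference values.
#'
#' @param x an [expr_matrix()] without weights requirement.
#' @return An [expr_matrix()] on the same scale.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  E <- x$E
  if (ncol(E) == 1L) {
    warning("single sample: quantile normalization is the identity")
    return(x)
  }
  ref <- rowMeans(apply(E, 2L, sort))
  out <- apply(E, 2L, function(col) {
    tmp <- numeric(length(col))
    tmp[order(col)] <- ref
    # tied values share the mean of the reference values they span
    stats::ave(tmp, match(col, col))
  })
  dimnames(out) <- dimnames(E)
  expr_matrix(out, scale = x$scale)
}

#' Principal component analysis of an expression matrix
#'
#' Feature-centered SVD of the samples: each feature's mean across samples
#' is removed, no scaling.  Intended for logged, filtered CPM.
#'
#' @param x an [expr_matrix()].
#' @param n_components number of components to keep (default
#'   `min(dim) - 1` capped at 10).
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components) and `variance_explained` (fractions over all
#'   components, so the retained ones sum to at most 1).
#' @export
pca_expr <- function(x, n_components = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$E) < 2L) stop("PCA needs at least 2 samples")
  kmax <- min(dim(x$E))
  n_components <- n_components %||% min(10L, kmax - 1L)
  if (n_components > kmax)
    stop("n_components exceeds min(n_features, n_samples) = ", kmax)
  pc <- prcomp(t(x$E), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(min(n_components, ncol(pc$x)))
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       variance_explained = ve[k])
}
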