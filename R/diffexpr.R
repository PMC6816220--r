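# Precision-weighted linear-model differential expression with
# empirical-Bayes variance moderation, written against count data through the
# log2-CPM transform with observation-level weights from the fitted
# mean-variance trend.

#' Observation-level precision weights from the count mean-variance trend
#'
#' Transforms counts to log2 CPM (prior count 0.5 on the count, 1 on the
#' library), fits each feature's linear model, estimates the mean-variance
#' trend by LOWESS of the square-root residual standard deviation against
#' average log2 count abundance, and converts the trend, evaluated at each
#' observation's fitted log2 count, into inverse-variance weights
#' (predicted sd to the power -4).  Predictions outside the fitted
#' abundance range are clipped to the trend's end values.
#'
#' @param x a [count_matrix()].
#' @param design numeric design matrix, rows aligned with samples; must be
#'   full column rank.
#' @param span LOWESS span (default 0.5).
#' @param prior_count log-CPM offset (default 0.5).
#' @param size_factors optional per-sample size factors.
#' @return An [expr_matrix()] with `E` = log2 CPM and `weights`.
#' @export
voom_weights <- function(x, design, span = 0.5, prior_count = 0.5,
                         size_factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  design <- as.matrix(design)
  n <- ncol(x$counts)
  if (nrow(design) != n) stop("design rows must match samples")
  if (qr(design)$rank < ncol(design)) stop("design matrix is not of full rank")
  d_resid <- n - ncol(design)
  if (d_resid < 2L) stop("need at least 2 residual degrees of freedom")
  lib <- lib_sizes(x)
  if (!is.null(size_factors)) {
    if (!is.null(names(size_factors))) size_factors <- size_factors[colnames(x$counts)]
    lib <- lib * size_factors
  }
  y <- t(log2(t(x$counts + prior_count) / (lib + 2 * prior_count) * 1e6))
  fit <- stats::lm.fit(design, t(y))
  sigma <- sqrt(colSums(as.matrix(fit$residuals)^2) / d_resid)
  # mean log2 count abundance and quarter-root residual variance
  sx <- rowMeans(y) + mean(log2(lib + 2 * prior_count)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy)
  if (sum(ok) < 2L) stop("too few features to fit a mean-variance trend")
  l <- lowess(sx[ok], sy[ok], f = span)
  trend <- stats::approxfun(l$x, l$y, rule = 2, ties = mean)
  fitted_y <- t(as.matrix(fit$fitted.values))
  fitted_logcount <- t(t(fitted_y) + log2(lib + 2 * prior_count)) - log2(1e6)
  w <- matrix(trend(fitted_logcount), nrow = nrow(y), dimnames = dimnames(y))^-4
  expr_matrix(y, weights = w, scale = "log2_cpm")
}

# Newton inversion of the trigamma function (y = trigamma(x), solve for x).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Moment-matching fit of the scaled-F model s^2 ~ s0^2 * F(d, d0) on log s^2:
# returns the prior df d0 and prior variance s0^2.  Features with zero
# residual variance or zero df are excluded from estimation.
fit_f_dist <- function(s2, d) {
  ok <- d > 0 & s2 > 0 & is.finite(s2)
  if (!any(ok)) stop("no features with positive residual variance and df")
  z <- log(s2[ok])
  dg <- digamma(d[ok] / 2)
  e <- z - dg + log(d[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(d[ok] / 2))
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s0_2 = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0_2 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Fit per-feature weighted linear models and moderate their variances
#'
#' For every feature, fits weighted least squares against `design`, then
#' shrinks the residual variances towards a common prior by fitting a
#' scaled-F distribution to them (moment matching on the log scale, with
#' the prior degrees of freedom obtained by trigamma inversion).  The
#' moderated t-statistic for the requested coefficient uses the posterior
#' variance `(d0 * s0^2 + d * s^2) / (d0 + d)` and `d + d0` degrees of
#' freedom; p-values are two-sided.
#'
#' @param x an [expr_matrix()], typically from [voom_weights()]; missing
#'   weights mean ordinary least squares.
#' @param design full-rank design matrix.
#' @param coef name or index of the design column to test.
#' @param d0 optional prior degrees of freedom override: `0` gives the
#'   classical per-feature t-test, `Inf` the pooled-variance t-test with
#'   `s0^2 = sum(d * s^2) / sum(d)`.
#' @param s0_2 optional prior variance override (used with finite `d0`).
#' @return List of class `model_fit` with elements `table` (a data.frame
#'   with `feature`, `logFC`, `aveExpr`, `t`, `p`, `adj_p` placeholder),
#'   `coefficients`, `s2`, `df_resid`, `stdev_unscaled`, `d0`, `s0_2`,
#'   `s2_post`.
#' @export
fit_and_moderate <- function(x, design, coef = 2L, d0 = NULL, s0_2 = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  design <- as.matrix(design)
  y <- x$E
  n <- ncol(y)
  p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match samples")
  if (qr(design)$rank < p) stop("design matrix is not of full rank")
  if (is.character(coef)) {
    coef <- match(coef, colnames(design))
    if (is.na(coef)) stop("coef not found among design columns")
  }
  G <- nrow(y)
  w <- x$weights
  beta <- matrix(NA_real_, G, p)
  s2 <- numeric(G)
  usd <- numeric(G)  # unscaled sd of the tested coefficient
  d_resid <- rep(n - p, G)
  for (g in seq_len(G)) {
    wg <- if (is.null(w)) rep(1, n) else w[g, ]
    sw <- sqrt(wg)
    Xw <- design * sw
    yw <- y[g, ] * sw
    qr_x <- qr(Xw)
    b <- qr.coef(qr_x, yw)
    res <- yw - Xw %*% b
    beta[g, ] <- b
    s2[g] <- sum(res^2) / (n - p)
    XtWX_inv <- chol2inv(qr.R(qr_x))
    usd[g] <- sqrt(XtWX_inv[coef, coef])
  }
  if (is.null(d0)) {
    fd <- fit_f_dist(s2, d_resid)
    d0 <- fd$d0
    s0_2 <- fd$s0_2
  } else if (is.infinite(d0)) {
    if (is.null(s0_2)) s0_2 <- sum(d_resid * s2) / sum(d_resid)
  } else if (d0 == 0) {
    s0_2 <- NA_real_
  } else if (is.null(s0_2)) {
    s0_2 <- fit_f_dist(s2, d_resid)$s0_2
  }
  s2_post <- if (d0 == 0) s2
             else if (is.infinite(d0)) rep(s0_2, G)
             else (d0 * s0_2 + d_resid * s2) / (d0 + d_resid)
  tstat <- beta[, coef] / (usd * sqrt(s2_post))
  df_total <- d_resid + d0
  pval <- 2 * pt(-abs(tstat), df = df_total)
  tab <- data.frame(feature = rownames(y),
                    logFC = beta[, coef],
                    aveExpr = rowMeans(y),
                    t = tstat, p = pval, adj_p = NA_real_,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, coefficients = beta, s2 = s2,
                 df_resid = d_resid, stdev_unscaled = usd,
                 d0 = d0, s0_2 = s0_2, s2_post = s2_post),
            class = "model_fit")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_p(i) = min over j >= i of min(1, m * p(j) / j)` on the sorted
#' p-values, returned in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- pmin(1, m * p[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Map a comparison name to (sample subset, logical group indicator).
# The positive group is the first-named condition of each comparison.
contrast_groups <- function(metadata, comparison, compartments = NULL) {
  comparison <- match.arg(comparison, CONTRASTS)
  md <- metadata
  if (comparison == "tumor_vs_normal") {
    md <- md[md$compartment %in% c("tumor", "normal"), , drop = FALSE]
    group <- md$compartment == "tumor"
  } else if (comparison == "exo_vs_serum") {
    md <- md[md$compartment %in% c("exosome", "serum"), , drop = FALSE]
    group <- md$compartment == "exosome"
  } else if (comparison == "cancer_vs_control_serum") {
    md <- md[md$compartment %in% c("serum", "control_serum"), , drop = FALSE]
    group <- md$compartment == "serum"
  } else {
    if (is.null(compartments))
      stop("clinical comparison '", comparison, "' needs a compartment subset")
    md <- md[md$compartment %in% compartments, , drop = FALSE]
    group <- switch(comparison,
                    HBV = md$hbv,
                    cirrhosis = md$cirrhosis,
                    surgery = md$surgery == "transplantation")
    keep <- !is.na(group)
    md <- md[keep, , drop = FALSE]
    group <- group[keep]
  }
  list(metadata = md, group = group)
}

#' Run one differential expression contrast end to end
#'
#' Composes expression filtering (within the contrast's samples), optional
#' calibrator size factors, precision weights, moderated-t model fitting
#' and Benjamini-Hochberg adjustment.  Comparisons: `tumor_vs_normal`
#' (tumor positive), `exo_vs_serum` (exosome positive),
#' `cancer_vs_control_serum` (cancer serum positive), and the clinical
#' contrasts `HBV`, `cirrhosis`, `surgery` (transplantation positive)
#' within a stated compartment.  Calibrator features never enter the
#' result table.
#'
#' @param x a [count_matrix()].
#' @param metadata sample metadata ([read_metadata()] layout).
#' @param comparison one of the comparisons above.
#' @param compartments compartment subset for clinical comparisons (e.g.
#'   `"serum"` for serum HBV contrasts).
#' @param adjust_for metadata columns entered as continuous covariates
#'   (typically `"sample_age"`).
#' @param paired add per-patient intercepts; requires complete pairs and
#'   drops incomplete ones.
#' @param alpha BH significance threshold (default 0.05).
#' @param min_cpm,min_fraction expression filter thresholds.
#' @param use_calibrators derive size factors from the spike-in
#'   calibrators and use them in all CPM computations.
#' @param span LOWESS span for the mean-variance trend.
#' @return A data.frame of class `de_result` with columns `feature`,
#'   `logFC`, `aveExpr`, `t`, `p`, `adj_p`, `significant`, plus
#'   attributes `contrast`, `n_group` (positive/negative sample counts),
#'   `d0` and `s0_2`.
#' @export
run_contrast <- function(x, metadata, comparison, compartments = NULL,
                         adjust_for = character(), paired = FALSE,
                         alpha = 0.05, min_cpm = 1, min_fraction = 0.5,
                         use_calibrators = FALSE, span = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  metadata <- metadata[metadata$sample_id %in% colnames(x$counts), , drop = FALSE]
  cg <- contrast_groups(metadata, comparison, compartments)
  md <- cg$metadata
  group <- cg$group
  if (paired) {
    if (is.null(md$patient_id)) stop("paired analysis needs patient_id")
    complete <- names(which(tapply(group, md$patient_id,
                                   function(g) any(g) && any(!g))))
    keep <- md$patient_id %in% complete
    md <- md[keep, , drop = FALSE]
    group <- group[keep]
  }
  if (!any(group) || !all(group %in% c(TRUE, FALSE)) || all(group))
    stop("both groups must be nonempty for comparison '", comparison, "'")
  xs <- x[, md$sample_id]
  sf <- if (use_calibrators) calibrator_size_factors(xs) else NULL
  xs <- filter_expressed(xs, min_cpm = min_cpm, min_fraction = min_fraction,
                         size_factors = sf)
  design <- cbind(`(Intercept)` = 1, group = as.numeric(group))
  for (cov in adjust_for) {
    v <- md[[cov]]
    if (is.null(v)) stop("covariate not in metadata: ", cov)
    if (anyNA(v)) stop("covariate '", cov, "' has missing values")
    design <- cbind(design, as.numeric(v))
    colnames(design)[ncol(design)] <- cov
  }
  if (paired) {
    pat <- factor(md$patient_id)
    if (nlevels(pat) > 1L) {
      pm <- stats::model.matrix(~pat)[, -1L, drop = FALSE]
      colnames(pm) <- paste0("patient_", levels(pat)[-1L])
      design <- cbind(design, pm)
    }
  }
  if (qr(design)$rank < ncol(design))
    stop("confounded design for '", comparison,
         "': group is collinear with covariates/pairing")
  xs_bio <- xs[!xs$is_calibrator, ]
  v <- voom_weights(xs_bio, design, span = span, size_factors = sf)
  fit <- fit_and_moderate(v, design, coef = "group")
  tab <- fit$table
  tab$adj_p <- bh_adjust(tab$p)
  tab$significant <- tab$adj_p < alpha
  attr(tab, "contrast") <- comparison
  attr(tab, "n_group") <- c(positive = sum(group), negative = sum(!group))
  attr(tab, "d0") <- fit$d0
  attr(tab, "s0_2") <- fit$s0_2
  class(tab) <- c("de_result", "data.frame")
  tab
}
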