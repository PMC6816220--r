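# Median-dichotomized expression survival analysis: Kaplan-Meier curves,
# two-group log-rank test, single-covariate Cox proportional hazards by
# Newton-Raphson on the Breslow partial likelihood, and a Bonferroni-adjusted
# per-feature screen.

#' Split patients at the median expression value
#'
#' `High` = strictly above the median; ties at the median go to `Low`.
#'
#' @param x named numeric vector of expression values (one per patient).
#' @return Character vector of `"High"`/`"Low"`, names preserved.
#' @export
dichotomize_by_median <- function(x) {
  if (length(x) < 2L) stop("need at least 2 patients")
  if (diff(range(x)) == 0) stop("all expression values identical: no median split")
  m <- median(x)
  setNames(ifelse(x > m, "High", "Low"), names(x))
}

check_survival_data <- function(sd) {
  need <- c("time_months", "event", "group")
  if (!all(need %in% names(sd)))
    stop("survival data needs columns: ", paste(need, collapse = ", "))
  if (any(sd$time_months < 0)) stop("negative survival times")
  sd
}

#' Kaplan-Meier product-limit curves
#'
#' One step function per group; censored patients leave the risk set
#' without a step.
#'
#' @param surv_data data.frame with `time_months`, `event` (logical) and
#'   `group`.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (rows at every distinct observed time per group,
#'   in time order).
#' @export
kaplan_meier <- function(surv_data) {
  surv_data <- check_survival_data(surv_data)
  do.call(rbind, lapply(split(surv_data, surv_data$group), function(g) {
    times <- sort(unique(g$time_months))
    n_risk <- vapply(times, function(t) sum(g$time_months >= t), numeric(1))
    n_event <- vapply(times, function(t)
      sum(g$time_months == t & g$event), numeric(1))
    n_censor <- vapply(times, function(t)
      sum(g$time_months == t & !g$event), numeric(1))
    data.frame(group = g$group[1L], time = times, n_risk = n_risk,
               n_event = n_event, n_censor = n_censor,
               surv = cumprod(1 - n_event / n_risk),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the distinct event
#' times: `chi2 = (sum(O1 - E1))^2 / sum(V)`, p from a chi-square with
#' 1 df.
#'
#' @param surv_data data.frame with `time_months`, `event`, `group` (two
#'   levels).
#' @return List with `chi2`, `p`, `observed` and `expected` per group.
#' @export
logrank_test <- function(surv_data) {
  surv_data <- check_survival_data(surv_data)
  groups <- sort(unique(surv_data$group))
  if (length(groups) != 2L) stop("log-rank test needs exactly two nonempty groups")
  if (!any(surv_data$event)) stop("log-rank test needs at least one event")
  g1 <- surv_data$group == groups[1L]
  times <- sort(unique(surv_data$time_months[surv_data$event]))
  o_minus_e <- 0; v <- 0; o1 <- 0; e1 <- 0
  for (t in times) {
    at_risk <- surv_data$time_months >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(surv_data$time_months == t & surv_data$event)
    d1 <- sum(surv_data$time_months == t & surv_data$event & g1)
    e <- d * n1 / n
    o1 <- o1 + d1; e1 <- e1 + e
    o_minus_e <- o_minus_e + (d1 - e)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE),
       observed = setNames(c(o1, sum(surv_data$event) - o1), groups),
       expected = setNames(c(e1, sum(surv_data$event) - e1), groups))
}

# Breslow partial log-likelihood, gradient and information for a single
# covariate x at coefficient beta.
breslow_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- x * beta
  ll <- 0; grad <- 0; info <- 0
  # walk event times; risk set = all with time >= t (Breslow: tied events
  # share the same risk set)
  for (t in unique(time[event])) {
    rs <- time >= t
    w <- exp(eta[rs])
    s0 <- sum(w)
    s1 <- sum(w * x[rs])
    s2 <- sum(w * x[rs]^2)
    ev <- time == t & event
    d <- sum(ev)
    ll <- ll + beta * sum(x[ev]) - d * log(s0)
    grad <- grad + sum(x[ev]) - d * s1 / s0
    info <- info + d * (s2 / s0 - (s1 / s0)^2)
  }
  list(ll = ll, grad = grad, info = info)
}

#' Cox proportional hazards fit for a binary group covariate
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson (start 0,
#' tolerance 1e-8, at most 50 iterations, step-halving when the
#' likelihood decreases).  Monotone likelihoods (complete separation of
#' event times) are flagged as non-converged with an absent p-value.
#'
#' @param surv_data data.frame with `time_months`, `event`, `group`; the
#'   coefficient is for `group == "High"` (or the second sorted level).
#' @return List with `beta`, `hr = exp(beta)`, `se`, `p` (two-sided
#'   Wald), `converged`, `score_chi2` (the score test at beta = 0, which
#'   for two tie-free groups equals the log-rank statistic).
#' @export
cox_fit <- function(surv_data) {
  surv_data <- check_survival_data(surv_data)
  groups <- sort(unique(surv_data$group))
  if (length(groups) != 2L) stop("cox_fit needs exactly two groups")
  ref <- if ("High" %in% groups) "High" else groups[2L]
  x <- as.numeric(surv_data$group == ref)
  time <- surv_data$time_months; event <- surv_data$event
  if (!any(event)) stop("no events")
  at0 <- breslow_loglik(0, time, event, x)
  score_chi2 <- if (at0$info > 0) at0$grad^2 / at0$info else 0
  beta <- 0; ll <- at0$ll; cur <- at0
  converged <- FALSE
  for (it in seq_len(50L)) {
    if (cur$info <= 0) break
    step <- cur$grad / cur$info
    new_beta <- beta + step
    new <- breslow_loglik(new_beta, time, event, x)
    halvings <- 0L
    while (new$ll < ll && halvings < 30L) {   # step-halving on decrease
      step <- step / 2
      new_beta <- beta + step
      new <- breslow_loglik(new_beta, time, event, x)
      halvings <- halvings + 1L
    }
    done <- abs(step) < 1e-8
    beta <- new_beta; ll <- new$ll; cur <- new
    if (done) { converged <- TRUE; break }
  }
  if (abs(beta) > 15) converged <- FALSE   # monotone likelihood / separation
  se <- if (cur$info > 0) 1 / sqrt(cur$info) else NA_real_
  p <- if (converged && is.finite(se))
    2 * stats::pnorm(-abs(beta / se)) else NA_real_
  list(beta = beta, hr = exp(beta), se = se, p = p,
       converged = converged, score_chi2 = score_chi2, loglik = ll)
}

#' Bonferroni-adjusted survival screen over expression features
#'
#' For each feature: dichotomize the patients at the median expression,
#' fit the two-group Cox model, and Bonferroni-adjust across the features
#' tested (`adj_p = min(1, m * p)`).
#'
#' @param expr an [expr_matrix()] with one column per patient (column
#'   names = patient ids).
#' @param surv_data data.frame with `patient_id`, `time_months`, `event`.
#' @param features features to test (default: all rows of `expr`).
#' @return data.frame with `feature`, `beta`, `hr`, `p`, `adj_p`,
#'   `converged`, sorted by p.
#' @export
survival_screen <- function(expr, surv_data, features = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!all(c("patient_id", "time_months", "event") %in% names(surv_data)))
    stop("surv_data needs patient_id, time_months, event")
  features <- features %||% rownames(expr$E)
  missing <- setdiff(features, rownames(expr$E))
  if (length(missing))
    stop("feature(s) not in expression matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  pats <- intersect(colnames(expr$E), surv_data$patient_id)
  if (length(pats) < 2L) stop("fewer than 2 patients shared between expr and surv_data")
  sd_use <- surv_data[match(pats, surv_data$patient_id), ]
  rows <- lapply(features, function(f) {
    grp <- dichotomize_by_median(expr$E[f, pats])
    fit <- cox_fit(data.frame(time_months = sd_use$time_months,
                              event = sd_use$event, group = unname(grp)))
    data.frame(feature = f, beta = fit$beta, hr = fit$hr, p = fit$p,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- length(features)
  out$adj_p <- pmin(1, m * out$p)
  out[order(out$p), c("feature", "beta", "hr", "p", "adj_p", "converged")]
}
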