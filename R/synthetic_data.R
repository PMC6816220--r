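# Synthetic multi-compartment cohort generator.  Emulates the statistical
# structure of a paired tumor / normal / serum / exosome small-RNA study:
# negative-binomial counts with compartment-specific RNA-class composition,
# spike-in calibrators with sample-independent abundance, a sample-age
# degradation confounder, planted differential-expression effects, a
# miRNA -> mRNA repression layer, and exponential survival times.

#' Declare a planted differential-expression effect
#'
#' @param feature_id feature carrying the effect (must exist in the
#'   simulated feature set).
#' @param contrast which comparison the effect belongs to: one of
#'   `tumor_vs_normal`, `exo_vs_serum`, `cancer_vs_control_serum`, `HBV`,
#'   `cirrhosis`, `surgery`.
#' @param log2fc finite log2 fold change applied multiplicatively to the
#'   contrast's positive group (tumor, exosome, cancer serum,
#'   HBV-positive, cirrhotic, transplantation, respectively).
#' @param compartments compartments in which the effect acts; defaults to
#'   the positive compartment of the contrast (`serum` for the clinical
#'   contrasts).
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(feature_id, contrast, log2fc, compartments = NULL) {
  contrast <- match.arg(contrast, CONTRASTS)
  if (!is.finite(log2fc)) stop("log2fc must be finite")
  if (is.null(compartments))
    compartments <- switch(contrast,
                           tumor_vs_normal = "tumor",
                           exo_vs_serum = "exosome",
                           cancer_vs_control_serum = "serum",
                           "serum")
  stopifnot(all(compartments %in% COMPARTMENTS))
  structure(list(feature_id = feature_id, contrast = contrast,
                 log2fc = log2fc, compartments = compartments),
            class = "planted_effect")
}

default_composition <- function() {
  rbind(
    tumor         = c(miRNA = 0.35, isomiR = 0, snoRNA = 0.30, tRNA = 0.15, scRNA = 0.05, other = 0.15),
    normal        = c(miRNA = 0.35, isomiR = 0, snoRNA = 0.30, tRNA = 0.15, scRNA = 0.05, other = 0.15),
    serum         = c(miRNA = 0.40, isomiR = 0, snoRNA = 0.05, tRNA = 0.20, scRNA = 0.20, other = 0.15),
    exosome       = c(miRNA = 0.50, isomiR = 0, snoRNA = 0.05, tRNA = 0.05, scRNA = 0.25, other = 0.15),
    control_serum = c(miRNA = 0.40, isomiR = 0, snoRNA = 0.05, tRNA = 0.20, scRNA = 0.20, other = 0.15))
}

#' Build a simulation configuration
#'
#' Defaults reproduce the study design the generator emulates: a discovery
#' cohort of 17 patients with four matched compartments plus 19 control
#' sera, a validation cohort of 80 patients, 10 spike-in calibrators,
#' tissue enriched for snoRNAs and exosomes depleted of tRNAs relative to
#' serum, a sample-age degradation confounder, and a miR-21-like feature
#' planted upregulated in both tumor-vs-normal and exosome-vs-serum.
#'
#' @param n_patients_discovery,n_patients_validation,n_controls cohort
#'   sizes (controls contribute serum only).
#' @param n_mirna number of miRNA features.
#' @param n_other_ncrna named counts for `snoRNA`, `tRNA`, `scRNA`,
#'   `other` features.
#' @param n_calibrators number of spike-in calibrators (>= 1).
#' @param n_genes number of mRNA genes for [simulate_mrna()].
#' @param nb_dispersion negative-binomial dispersion `phi`
#'   (variance `mu + phi * mu^2`), shared across features.
#' @param lib_size_range range of per-sample library sizes (log-uniform).
#' @param class_composition matrix compartment x RNA class, rows on the
#'   simplex.
#' @param planted_effects list of [planted_effect()] objects.
#' @param age_effect_sd sd of the per-feature log2 abundance slope per
#'   unit of sample age (0 disables the confounder).
#' @param target_density probability that a decoy (miRNA, gene) pair
#'   appears in the predicted-target table.
#' @param repression_slope nonpositive log2 mRNA change per unit centered
#'   log2 miRNA expression for planted repressed pairs.
#' @param survival_beta log hazard ratio of the high-expression group.
#' @param censor_rate expected fraction of censored patients in \[0, 1\].
#' @param seed integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients_discovery = 17L,
                       n_patients_validation = 80L,
                       n_controls = 19L,
                       n_mirna = 300L,
                       n_other_ncrna = c(snoRNA = 100L, tRNA = 60L,
                                         scRNA = 20L, other = 120L),
                       n_calibrators = 10L,
                       n_genes = 2000L,
                       nb_dispersion = 0.2,
                       lib_size_range = c(2e6, 2e7),
                       class_composition = default_composition(),
                       planted_effects = list(
                         planted_effect("miR-0001", "tumor_vs_normal", 2),
                         planted_effect("miR-0001", "exo_vs_serum", 2),
                         planted_effect("miR-0002", "cancer_vs_control_serum", 1.95),
                         planted_effect("miR-0002", "HBV", 2.929, "serum")),
                       age_effect_sd = 0.05,
                       target_density = 0.02,
                       repression_slope = -1,
                       survival_beta = log(2),
                       censor_rate = 0.3,
                       seed = 1L) {
  cfg <- list(n_patients_discovery = as.integer(n_patients_discovery),
              n_patients_validation = as.integer(n_patients_validation),
              n_controls = as.integer(n_controls),
              n_mirna = as.integer(n_mirna),
              n_other_ncrna = n_other_ncrna,
              n_calibrators = as.integer(n_calibrators),
              n_genes = as.integer(n_genes),
              nb_dispersion = nb_dispersion,
              lib_size_range = lib_size_range,
              class_composition = class_composition,
              planted_effects = planted_effects,
              age_effect_sd = age_effect_sd,
              target_density = target_density,
              repression_slope = repression_slope,
              survival_beta = survival_beta,
              censor_rate = censor_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_calibrators >= 1L, cfg$nb_dispersion >= 0,
            cfg$n_mirna >= 1L, cfg$n_genes >= 0L)
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stop("censor_rate must be in [0, 1]")
  if (cfg$age_effect_sd < 0) stop("age_effect_sd must be >= 0")
  if (cfg$repression_slope > 0) stop("repression_slope must be <= 0 (repression only)")
  if (length(cfg$lib_size_range) != 2L || any(cfg$lib_size_range <= 0))
    stop("lib_size_range must be two positive numbers")
  cc <- cfg$class_composition
  if (!all(rownames(cc) %in% COMPARTMENTS) || !all(colnames(cc) %in% RNA_CLASSES))
    stop("class_composition must be compartment x RNA class")
  if (any(abs(rowSums(cc) - 1) > 1e-9))
    stop("each class_composition row must sum to 1")
  if (any(cc < 0)) stop("class_composition entries must be nonnegative")
  for (pe in cfg$planted_effects)
    if (!inherits(pe, "planted_effect")) stop("planted_effects must be planted_effect objects")
  structure(cfg, class = "sim_config")
}

# Sample metadata frame for one configured cohort.
sim_metadata <- function(cfg) {
  pats <- c(sprintf("D%03d", seq_len(cfg$n_patients_discovery)),
            sprintf("V%03d", seq_len(cfg$n_patients_validation)))
  cohort <- rep(c("discovery", "validation"),
                c(cfg$n_patients_discovery, cfg$n_patients_validation))
  comp4 <- c("tumor", "normal", "serum", "exosome")
  md <- data.frame(
    sample_id = paste(rep(pats, each = 4L), comp4, sep = "_"),
    patient_id = rep(pats, each = 4L),
    compartment = rep(comp4, length(pats)),
    cohort = rep(cohort, each = 4L),
    stringsAsFactors = FALSE)
  if (cfg$n_controls > 0L) {
    ctl <- sprintf("C%03d", seq_len(cfg$n_controls))
    md <- rbind(md, data.frame(sample_id = paste0(ctl, "_serum"),
                               patient_id = NA_character_,
                               compartment = "control_serum",
                               cohort = "discovery",
                               stringsAsFactors = FALSE))
  }
  # one specimen age per patient (tissue and blood archived together)
  age_by_pat <- setNames(runif(length(pats), 0, 10), pats)
  md$sample_age <- ifelse(is.na(md$patient_id),
                          runif(nrow(md), 0, 10), age_by_pat[md$patient_id])
  hbv <- setNames(runif(length(pats)) < 0.4, pats)
  cirr <- setNames(runif(length(pats)) < 0.5, pats)
  surg <- setNames(ifelse(runif(length(pats)) < 0.6, "resection",
                          "transplantation"), pats)
  md$hbv <- ifelse(is.na(md$patient_id), NA, hbv[md$patient_id])
  md$cirrhosis <- ifelse(is.na(md$patient_id), NA, cirr[md$patient_id])
  md$surgery <- ifelse(is.na(md$patient_id), NA_character_, surg[md$patient_id])
  md
}

# Samples forming the positive group of a planted effect.
effect_samples <- function(pe, md) {
  in_scope <- md$compartment %in% pe$compartments
  pos <- switch(pe$contrast,
                tumor_vs_normal = md$compartment == "tumor",
                exo_vs_serum = md$compartment == "exosome",
                cancer_vs_control_serum = md$compartment == "serum" &
                  !is.na(md$patient_id),
                HBV = !is.na(md$hbv) & md$hbv,
                cirrhosis = !is.na(md$cirrhosis) & md$cirrhosis,
                surgery = !is.na(md$surgery) & md$surgery == "transplantation")
  md$sample_id[in_scope & pos]
}

#' Simulate a paired-compartment small RNA count cohort
#'
#' Per-feature baseline abundances are drawn per RNA class and rescaled
#' within each compartment so that the expected read mass per class equals
#' the configured composition.  Counts are negative binomial around
#' `library size x relative abundance`, with library sizes log-uniform in
#' the configured range.  Sample age multiplies the true abundance of every
#' non-calibrator feature by `2^(slope_f * age)` with per-feature slopes
#' `N(0, age_effect_sd)` (degradation acts before sampling).  Calibrators
#' keep a compartment- and age-independent mean.  Planted effects multiply
#' the positive-group mean by `2^log2fc`.  Fully deterministic given the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `metadata`
#'   (data.frame) and `truth` (data.frame of planted effects).
#' @export
simulate_cohort <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  with_rng(cfg$seed, {
    n_oth <- cfg$n_other_ncrna
    ids <- c(sprintf("miR-%04d", seq_len(cfg$n_mirna)),
             unlist(lapply(names(n_oth), function(k)
               if (n_oth[[k]] > 0) sprintf("%s-%04d", k, seq_len(n_oth[[k]])) else character(0))),
             sprintf("cal-%02d", seq_len(cfg$n_calibrators)))
    cls <- c(rep("miRNA", cfg$n_mirna),
             rep(names(n_oth), unlist(n_oth)),
             rep("other", cfg$n_calibrators))
    is_cal <- c(rep(FALSE, cfg$n_mirna + sum(unlist(n_oth))),
                rep(TRUE, cfg$n_calibrators))
    md <- sim_metadata(cfg)
    for (pe in cfg$planted_effects)
      if (!pe$feature_id %in% ids[!is_cal])
        stop("planted feature id not among simulated features: ", pe$feature_id)

    bio <- !is_cal
    a <- rlnorm(sum(bio), meanlog = 0, sdlog = 1.5)   # baseline abundance
    class_bio <- cls[bio]
    # per-compartment relative abundance: class mass matches composition
    comp_of <- md$compartment
    rel <- matrix(0, sum(bio), nrow(md),
                  dimnames = list(ids[bio], md$sample_id))
    for (cp in unique(comp_of)) {
      r <- numeric(sum(bio))
      for (k in unique(class_bio)) {
        in_k <- class_bio == k
        mass <- cfg$class_composition[cp, k]
        if (mass > 0 && any(in_k)) r[in_k] <- a[in_k] / sum(a[in_k]) * mass
      }
      r <- r / sum(r)  # guard against classes configured > 0 but absent
      rel[, comp_of == cp] <- r
    }
    lib <- exp(runif(nrow(md), log(cfg$lib_size_range[1]), log(cfg$lib_size_range[2])))
    mu <- t(t(rel) * lib)
    if (cfg$age_effect_sd > 0) {
      slope <- rnorm(sum(bio), 0, cfg$age_effect_sd)
      mu <- mu * 2^(outer(slope, md$sample_age))
    }
    for (pe in cfg$planted_effects) {
      s <- effect_samples(pe, md)
      if (length(s)) mu[pe$feature_id, s] <- mu[pe$feature_id, s] * 2^pe$log2fc
    }
    if (any(!is.finite(mu))) stop("non-finite simulated means")
    draw_nb <- function(m) {
      if (cfg$nb_dispersion < 1e-8) rpois(length(m), m)
      else rnbinom(length(m), mu = m, size = 1 / cfg$nb_dispersion)
    }
    counts <- matrix(draw_nb(mu), nrow(mu), dimnames = dimnames(mu))
    cal_mean <- rlnorm(cfg$n_calibrators, meanlog = log(5000), sdlog = 0.5)
    cal_mu <- matrix(cal_mean, cfg$n_calibrators, nrow(md),
                     dimnames = list(ids[is_cal], md$sample_id))
    cal_counts <- matrix(draw_nb(cal_mu), nrow(cal_mu), dimnames = dimnames(cal_mu))
    all_counts <- rbind(counts, cal_counts)[ids, , drop = FALSE]
    truth <- do.call(rbind, lapply(cfg$planted_effects, function(pe)
      data.frame(feature_id = pe$feature_id, contrast = pe$contrast,
                 log2fc = pe$log2fc,
                 compartments = paste(pe$compartments, collapse = ";"),
                 stringsAsFactors = FALSE)))
    list(counts = count_matrix(all_counts, cls, is_cal),
         metadata = md,
         truth = truth %||% data.frame(feature_id = character(0),
                                       contrast = character(0),
                                       log2fc = numeric(0),
                                       compartments = character(0)))
  })
}

#' Simulate mRNA expression with planted miRNA repression
#'
#' Gene log2 expression is Gaussian noise around a per-gene baseline; for
#' every planted repressed pair the gene tracks its miRNA:
#' `gene = baseline + repression_slope * centered(log2 miRNA) + noise`.
#' The returned predicted-target table contains all planted pairs with
#' context scores drawn U(-1, -0.45) (safely below the -0.4 selection
#' cut) plus decoy pairs sampled at `target_density` with scores
#' U(-1, 0).
#'
#' @param cfg a [sim_config()] (uses `n_genes`, `target_density`,
#'   `repression_slope`, `seed`).
#' @param mirna_expr [expr_matrix()] of log2 miRNA expression; its samples
#'   define the mRNA samples.
#' @param mirna_truth named numeric vector of planted miRNA log2 fold
#'   changes (names must be rows of `mirna_expr`); each gets
#'   `pairs_per_mirna` repressed genes.
#' @param pairs_per_mirna planted repressed genes per planted miRNA.
#' @param noise_sd residual sd of gene log2 expression.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @return List with `expr` (genes x samples [expr_matrix()],
#'   log2_intensity), `targets` (target table data.frame) and `truth`
#'   (data.frame of planted pairs).
#' @export
simulate_mrna <- function(cfg, mirna_expr, mirna_truth,
                          pairs_per_mirna = 1L, noise_sd = 0.5,
                          baseline_mean = 8, baseline_sd = 2) {
  cfg <- validate_sim_config(cfg)
  stopifnot(inherits(mirna_expr, "expr_matrix"))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$target_density < 0 || cfg$target_density > 1)
    stop("target_density must be in [0, 1]")
  missing <- setdiff(names(mirna_truth), rownames(mirna_expr$E))
  if (length(missing))
    stop("planted miRNA(s) not in mirna_expr: ", paste(missing, collapse = ", "))
  n_planted <- length(mirna_truth) * pairs_per_mirna
  if (n_planted > cfg$n_genes) stop("more planted pairs than genes")
  with_rng(cfg$seed + 1L, {
    genes <- sprintf("gene-%04d", seq_len(cfg$n_genes))
    samples <- colnames(mirna_expr$E)
    ns <- length(samples)
    base <- rnorm(cfg$n_genes, baseline_mean, baseline_sd)
    E <- matrix(rnorm(cfg$n_genes * ns, 0, noise_sd), cfg$n_genes, ns,
                dimnames = list(genes, samples)) + base
    truth <- data.frame(mirna_id = character(0), gene_id = character(0),
                        stringsAsFactors = FALSE)
    if (n_planted > 0) {
      gi <- 0L
      for (m in names(mirna_truth)) {
        xm <- mirna_expr$E[m, ]
        xc <- xm - mean(xm)
        for (j in seq_len(pairs_per_mirna)) {
          gi <- gi + 1L
          E[gi, ] <- base[gi] + cfg$repression_slope * xc +
            rnorm(ns, 0, noise_sd)
          truth <- rbind(truth, data.frame(mirna_id = m, gene_id = genes[gi],
                                           stringsAsFactors = FALSE))
        }
      }
    }
    mirnas <- rownames(mirna_expr$E)
    decoy <- which(matrix(runif(length(mirnas) * cfg$n_genes),
                          length(mirnas)) < cfg$target_density, arr.ind = TRUE)
    targets <- data.frame(mirna_id = mirnas[decoy[, 1L]],
                          gene_id = genes[decoy[, 2L]],
                          weighted_context_score = runif(nrow(decoy), -1, 0),
                          stringsAsFactors = FALSE)
    if (nrow(truth)) {
      planted <- data.frame(mirna_id = truth$mirna_id, gene_id = truth$gene_id,
                            weighted_context_score = runif(nrow(truth), -1, -0.45),
                            stringsAsFactors = FALSE)
      key <- function(d) paste(d$mirna_id, d$gene_id)
      targets <- rbind(planted, targets[!key(targets) %in% key(planted), ])
    }
    rownames(targets) <- NULL
    list(expr = expr_matrix(E, scale = "log2_intensity"),
         targets = validate_targets(targets), truth = truth)
  })
}

#' Simulate survival times for dichotomized patients
#'
#' Event times are exponential; the high-expression group's hazard is
#' multiplied by `exp(survival_beta)`.  Censoring times are independent
#' uniform on (0, c) with c solved numerically so the expected censored
#' fraction equals `censor_rate`.
#'
#' @param patient_id character vector of patient ids.
#' @param group logical (or "High"/"Low") per patient: TRUE = high group.
#' @param survival_beta log hazard ratio for the high group.
#' @param censor_rate expected censored fraction in \[0, 1).
#' @param seed RNG seed.
#' @param baseline_median baseline median survival in months (default 24).
#' @return data.frame of class `survival_data` with `patient_id`,
#'   `time_months`, `event`, `group` ("High"/"Low").
#' @export
simulate_survival <- function(patient_id, group, survival_beta = 0,
                              censor_rate = 0, seed = 1L,
                              baseline_median = 24) {
  if (is.character(group) || is.factor(group)) group <- as.character(group) == "High"
  stopifnot(length(group) == length(patient_id), !anyNA(group))
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  with_rng(seed, {
    lam0 <- log(2) / baseline_median
    lam <- lam0 * exp(survival_beta * group)
    tt <- rexp(length(lam), rate = lam)
    if (censor_rate == 0) {
      time <- tt; event <- rep(TRUE, length(tt))
    } else {
      pc <- function(cc) mean((1 - exp(-lam * cc)) / (lam * cc)) - censor_rate
      cmax <- uniroot(pc, c(1e-8, 1e8), tol = 1e-10)$root
      cens <- runif(length(tt), 0, cmax)
      event <- tt <= cens
      time <- pmin(tt, cens)
    }
    structure(data.frame(patient_id = patient_id, time_months = time,
                         event = event,
                         group = ifelse(group, "High", "Low"),
                         stringsAsFactors = FALSE),
              class = c("survival_data", "data.frame"))
  })
}

#' Write a simulated cohort as the standard pipeline inputs
#'
#' Emits counts TSV + feature annotation TSV, metadata CSV, target table
#' TSV, mRNA expression TSV, survival CSV and a truth JSON.
#'
#' @param sim list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param mrna optional list from [simulate_mrna()].
#' @param survival_data optional [simulate_survival()] result.
#' @return Named character vector of the files written.
#' @export
write_simulation <- function(sim, dir, mrna = NULL, survival_data = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(counts = file.path(dir, "counts.tsv"),
             features = file.path(dir, "counts_features.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.json"))
  write_counts(sim$counts, files[["counts"]], files[["features"]])
  write_metadata(sim$metadata, files[["metadata"]])
  truth <- list(planted_effects = sim$truth)
  if (!is.null(mrna)) {
    files <- c(files, targets = file.path(dir, "targets.tsv"),
               mrna = file.path(dir, "mrna_expr.tsv"))
    write_targets(mrna$targets, files[["targets"]])
    write_expr(mrna$expr, files[["mrna"]])
    truth$planted_pairs <- mrna$truth
  }
  if (!is.null(survival_data)) {
    files <- c(files, survival = file.path(dir, "survival.csv"))
    utils::write.csv(survival_data, files[["survival"]], row.names = FALSE,
                     quote = FALSE)
  }
  jsonlite::write_json(truth, files[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  files
}
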