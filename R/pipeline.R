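# Config-driven orchestration: simulate (or ingest) -> normalize -> DE per
# contrast -> concordance -> target cascade -> survival, with a JSON run
# manifest recording parameters, outputs and content hashes.

default_thresholds <- function() {
  list(alpha = 0.05, min_cpm = 1, min_fraction = 0.5,
       percentile = 75, expr_threshold = 10, score_cutoff = -0.4,
       direction_fraction = 0.75, enrichment_cutoff = 0.01)
}

#' Validate a pipeline configuration
#'
#' A config is a list (or YAML file) with an `out_dir`, a `seed`, either a
#' `simulate` block (arguments for [sim_config()]) or an `inputs` block
#' (paths: `counts`, `metadata`, optionally `targets`, `mrna_expr`,
#' `survival`, `gmt`), a `contrasts` list (each with `comparison` and
#' optionally `compartments`, `adjust_for`, `paired`), and optional
#' `thresholds` overriding the defaults (`alpha` 0.05, `min_cpm` 1,
#' `min_fraction` 0.5, `percentile` 75, `expr_threshold` 10,
#' `score_cutoff` -0.4, `direction_fraction` 0.75, `enrichment_cutoff`
#' 0.01).
#'
#' @param config list or path to a YAML file.
#' @return The normalized config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (isTRUE(config$simulate)) config$simulate <- list()
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs either a simulate block or an inputs block")
  if (!is.null(config$inputs)) {
    if (is.null(config$inputs$counts) || is.null(config$inputs$metadata))
      stop("inputs block needs counts and metadata paths")
    for (p in unlist(config$inputs))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  th <- default_thresholds()
  for (nm in names(config$thresholds)) {
    if (!nm %in% names(th)) stop("unknown threshold: ", nm)
    th[[nm]] <- config$thresholds[[nm]]
  }
  stopifnot(th$alpha > 0, th$alpha < 1, th$min_fraction >= 0,
            th$min_fraction <= 1, th$direction_fraction >= 0,
            th$direction_fraction <= 1)
  config$thresholds <- th
  if (is.null(config$contrasts))
    config$contrasts <- list(list(comparison = "tumor_vs_normal", paired = TRUE),
                             list(comparison = "exo_vs_serum"))
  config
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

run_stage <- function(stage, fun) {
  log_stage(stage, "start")
  tryCatch(fun(), error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writes every artifact under
#' `config$out_dir`, and returns (and writes) a run manifest listing
#' parameters, per-stage outputs and an md5 hash of every file, so that a
#' rerun with the same config and seed is verifiably identical.  A stage
#' failure halts the run with the failing stage named; files already
#' written are retained.
#'
#' @param config list or YAML path (see [pipeline_config()]).
#' @return The manifest list, invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  th <- config$thresholds
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())   # shared pipeline state
  st$files <- character(0)
  st$mrna <- NULL; st$targets <- NULL; st$surv_in <- NULL; st$gmt <- NULL

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    st$cfg <- do.call(sim_config, sim_args)
    st$sim <- run_stage("simulate", function() simulate_cohort(st$cfg))
    st$counts <- st$sim$counts
    st$metadata <- st$sim$metadata
    st$files <- c(st$files, write_simulation(st$sim, out))
  } else {
    run_stage("ingest", function() {
      st$counts <- read_counts(config$inputs$counts)
      st$metadata <- read_metadata(config$inputs$metadata)
      if (!is.null(config$inputs$targets))
        st$targets <- read_targets(config$inputs$targets)
      if (!is.null(config$inputs$mrna_expr))
        st$mrna <- list(expr = read_expr(config$inputs$mrna_expr))
      if (!is.null(config$inputs$survival))
        st$surv_in <- utils::read.csv(config$inputs$survival)
      if (!is.null(config$inputs$gmt)) st$gmt <- read_gmt(config$inputs$gmt)
    })
  }

  run_stage("normalize", function() {
    st$sf <- calibrator_size_factors(st$counts)
    st$filt <- filter_expressed(st$counts, min_cpm = th$min_cpm,
                                min_fraction = th$min_fraction,
                                size_factors = st$sf)
    st$expr <- cpm(st$filt[!st$filt$is_calibrator, ], log = TRUE,
                   size_factors = st$sf)
    f <- file.path(out, "expr_log2cpm.tsv")
    write_expr(st$expr, f)
    st$files <- c(st$files, normalized_expr = f)
  })

  run_stage("diffexpr", function() {
    st$de <- list()
    for (ct in config$contrasts) {
      de <- run_contrast(st$counts, st$metadata,
                         comparison = ct$comparison,
                         compartments = ct$compartments,
                         adjust_for = ct$adjust_for %||% character(0),
                         paired = isTRUE(ct$paired),
                         alpha = th$alpha, min_cpm = th$min_cpm,
                         min_fraction = th$min_fraction,
                         use_calibrators = TRUE)
      f <- file.path(out, paste0("de_", ct$comparison, ".tsv"))
      write_de(de, f)
      st$files <- c(st$files, setNames(f, paste0("de_", ct$comparison)))
      st$de[[ct$comparison]] <- de
    }
  })

  if (all(c("tumor_vs_normal", "exo_vs_serum") %in% names(st$de)))
    run_stage("concordance", function() {
      expressed <- lapply(c("tumor", "normal", "serum", "exosome"), function(cp) {
        ids <- intersect(st$metadata$sample_id[st$metadata$compartment == cp],
                         colnames(st$counts$counts))
        fe <- filter_expressed(st$counts[, ids], min_cpm = th$min_cpm,
                               min_fraction = th$min_fraction)
        rownames(fe$counts)[!fe$is_calibrator]
      })
      st$concord <- compare_contrasts(st$de$tumor_vs_normal,
                                      st$de$exo_vs_serum,
                                      expressed, alpha = th$alpha)
      f <- file.path(out, "concordance.json")
      cr <- st$concord
      jsonlite::write_json(
        list(union_significant = cr$union_significant,
             expressed_in_all = cr$expressed_in_all,
             same_sign = cr$same_sign,
             both_significant = cr$both_significant,
             both_significant_same_sign = cr$both_significant_same_sign,
             pearson_r = cr$pearson_r,
             counts = lapply(cr[1:5], length)),
        f, auto_unbox = TRUE, digits = NA, null = "null")
      st$files <- c(st$files, concordance = f)
    })

  if (!is.null(st$de$tumor_vs_normal) &&
      (!is.null(config$simulate) || !is.null(st$targets)))
    run_stage("cascade", function() {
      de <- st$de$tumor_vs_normal
      de_sig <- de[de$significant, , drop = FALSE]
      tumor_ids <- intersect(
        st$metadata$sample_id[st$metadata$compartment == "tumor"],
        colnames(st$expr$E))
      mir_rows <- rownames(st$expr$E)[
        st$filt$feature_class[rownames(st$expr$E)] == "miRNA"]
      mirna_tumor <- expr_matrix(st$expr$E[mir_rows, tumor_ids, drop = FALSE],
                                 scale = "log2_cpm")
      if (!is.null(config$simulate)) {
        tr <- st$sim$truth
        truth_fc <- setNames(tr$log2fc, tr$feature_id)[
          tr$contrast == "tumor_vs_normal"]
        truth_fc <- truth_fc[names(truth_fc) %in% rownames(mirna_tumor$E)]
        sim_m <- simulate_mrna(st$cfg, mirna_tumor, truth_fc)
        st$targets <- sim_m$targets
        st$mrna <- sim_m
        ft <- file.path(out, "targets.tsv")
        fm <- file.path(out, "mrna_expr.tsv")
        write_targets(sim_m$targets, ft)
        write_expr(sim_m$expr, fm)
        st$files <- c(st$files, targets = ft, mrna_expr = fm)
      }
      if (is.null(st$mrna)) {
        log_stage("cascade", "skipped: no mRNA expression available")
      } else {
        st$cascade <- run_cascade(de_sig, st$targets, mirna_tumor,
                                  st$mrna$expr,
                                  percentile = th$percentile,
                                  expr_threshold = th$expr_threshold,
                                  score_cutoff = th$score_cutoff,
                                  min_fraction = th$direction_fraction)
        fp <- file.path(out, "cascade_pairs.tsv")
        write.table(st$cascade$retained_pairs, fp, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        fa <- file.path(out, "cascade_attrition.json")
        jsonlite::write_json(as.list(st$cascade$attrition), fa,
                             auto_unbox = TRUE)
        st$files <- c(st$files, cascade_pairs = fp, cascade_attrition = fa)
        if (!is.null(st$gmt)) {
          enr <- enrich_gene_sets(st$cascade$retained_genes,
                                  rownames(st$mrna$expr$E), st$gmt,
                                  p_cutoff = th$enrichment_cutoff)
          fe <- file.path(out, "enrichment.tsv")
          write.table(enr, fe, sep = "\t", quote = FALSE, row.names = FALSE)
          st$files <- c(st$files, enrichment = fe)
        }
      }
    })

  run_stage("survival", function() {
    md <- st$metadata
    tumor_ids <- md$sample_id[md$compartment == "tumor" & !is.na(md$patient_id)]
    tumor_ids <- intersect(tumor_ids, colnames(st$expr$E))
    if (length(tumor_ids) < 4L) {
      log_stage("survival", "skipped: fewer than 4 tumor samples")
    } else {
      emat <- st$expr$E[, tumor_ids, drop = FALSE]
      colnames(emat) <- md$patient_id[match(tumor_ids, md$sample_id)]
      tumor_expr <- expr_matrix(emat, scale = "log2_cpm")
      if (!is.null(config$simulate)) {
        tr <- st$sim$truth
        marker <- tr$feature_id[tr$contrast == "tumor_vs_normal"][1L]
        if (is.na(marker) || !marker %in% rownames(emat))
          marker <- rownames(emat)[which.max(rowMeans(emat))]
        grp <- dichotomize_by_median(emat[marker, ])
        st$surv_in <- simulate_survival(colnames(emat), grp == "High",
                                        survival_beta = st$cfg$survival_beta,
                                        censor_rate = st$cfg$censor_rate,
                                        seed = config$seed + 2L)
        f <- file.path(out, "survival.csv")
        utils::write.csv(st$surv_in, f, row.names = FALSE, quote = FALSE)
        st$files <- c(st$files, survival = f)
      }
      if (is.null(st$surv_in)) {
        log_stage("survival", "skipped: no survival data available")
      } else {
        mir_rows <- rownames(emat)[
          st$filt$feature_class[rownames(emat)] == "miRNA"]
        st$screen <- survival_screen(tumor_expr, st$surv_in,
                                     features = mir_rows)
        f <- file.path(out, "survival_screen.tsv")
        write.table(st$screen, f, sep = "\t", quote = FALSE, row.names = FALSE)
        st$files <- c(st$files, survival_screen = f)
      }
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirc")),
    seed = config$seed,
    thresholds = th,
    contrasts = config$contrasts,
    files = lapply(st$files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_stage("done", "manifest written to ", file.path(out, "manifest.json"))
  invisible(manifest)
}
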