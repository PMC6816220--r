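#' Construct a count matrix with feature annotation
#'
#' A `count_matrix` couples a nonnegative integer feature-by-sample matrix
#' with its feature annotation: the RNA class of every feature (miRNA,
#' isomiR, snoRNA, tRNA, scRNA or other) and a flag marking spike-in
#' calibrator features.  Calibrators are synthetic RNAs added in fixed
#' amounts during library preparation; they are excluded from library sizes
#' and from biological summaries, and drive [calibrator_size_factors()].
#'
#' @param counts integer matrix (features x samples) with unique row and
#'   column names.
#' @param feature_class character vector, one RNA class per feature, values
#'   in `miRNA`, `isomiR`, `snoRNA`, `tRNA`, `scRNA`, `other`.
#' @param is_calibrator logical vector flagging calibrator features.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, feature_class, is_calibrator = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    rows <- unique(rownames(counts)[(bad - 1L) %% nrow(counts) + 1L])
    stop("counts must be nonnegative integers; offending feature(s): ",
         paste(head(rows, 5L), collapse = ", "))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  if (is.null(is_calibrator)) is_calibrator <- rep(FALSE, nrow(counts))
  feature_class <- as.character(feature_class)
  is_calibrator <- as.logical(is_calibrator)
  if (length(feature_class) != nrow(counts) || length(is_calibrator) != nrow(counts))
    stop("feature_class and is_calibrator must have one entry per feature")
  if (anyNA(is_calibrator)) stop("is_calibrator must be TRUE/FALSE")
  unknown <- setdiff(unique(feature_class), RNA_CLASSES)
  if (length(unknown))
    stop("unknown RNA class(es): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(RNA_CLASSES, collapse = ", "), ")")
  structure(list(counts = counts,
                 feature_class = setNames(feature_class, rownames(counts)),
                 is_calibrator = setNames(is_calibrator, rownames(counts))),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%d calibrators)\n",
              nrow(x$counts), ncol(x$counts), sum(x$is_calibrator)))
  cls <- table(x$feature_class)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a count matrix
#'
#' @param x a `count_matrix`.
#' @param i,j feature and sample indices (names, logical or integer).
#' @param ... ignored.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               unname(x$feature_class[i]), unname(x$is_calibrator[i]))
}

#' Construct a (log) expression matrix with optional precision weights
#'
#' @param E numeric matrix (features x samples).
#' @param weights optional positive matrix of the same shape, one precision
#'   weight per observation.
#' @param scale one of `"log2_cpm"`, `"cpm"`, `"log2_intensity"` recording
#'   what the values are.
#' @return An object of class `expr_matrix` with elements `E`, `weights`,
#'   `scale`.
#' @export
expr_matrix <- function(E, weights = NULL, scale = "log2_cpm") {
  E <- as.matrix(E)
  scale <- match.arg(scale, c("log2_cpm", "cpm", "log2_intensity"))
  if (any(!is.finite(E))) stop("expression values must be finite")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(E))) stop("weights must match E in shape")
    if (any(!is.finite(weights) | weights <= 0)) stop("weights must be positive")
  }
  structure(list(E = E, weights = weights, scale = scale), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$E)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$E)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d features x %d samples%s\n", x$scale,
              nrow(x$E), ncol(x$E),
              if (is.null(x$weights)) "" else ", with weights"))
  invisible(x)
}

# ---- readers / writers ------------------------------------------------------

#' Read a count matrix from TSV or MatrixMarket
#'
#' The TSV layout is a header row of sample ids and a first column of
#' feature ids.  A MatrixMarket file (`.mtx`) needs sidecar id files
#' `<stem>.rows.txt` and `<stem>.cols.txt`.  Feature annotation (columns
#' `feature_id`, `class`, `is_calibrator`) is read from `annotation`,
#' defaulting to `<stem>_features.tsv` next to the counts file.
#'
#' Malformed input (ragged rows, negative or fractional counts, duplicate
#' ids, unknown RNA class) is rejected with an error naming the offender,
#' never coerced.
#'
#' @param path counts file (`.tsv`/`.txt` or `.mtx`).
#' @param annotation path to the feature annotation TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  stem <- sub("\\.(tsv|txt|mtx)$", "", path)
  if (is.null(annotation)) annotation <- paste0(stem, "_features.tsv")
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(stem, ".rows.txt"))
    cn <- readLines(paste0(stem, ".cols.txt"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar id files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    if (!ncol(df) >= 2) stop("counts TSV needs a feature id column plus samples")
    ids <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) {
      bad <- ids[apply(is.na(m), 1L, any)]
      stop("non-numeric count(s) in feature(s): ", paste(head(bad, 5L), collapse = ", "))
    }
    rownames(m) <- ids
  }
  neg <- rownames(m)[apply(m < 0 | m != round(m), 1L, any)]
  if (length(neg))
    stop("negative or non-integer counts in feature(s): ",
         paste(head(neg, 5L), collapse = ", "))
  if (!file.exists(annotation))
    stop("feature annotation file not found: ", annotation)
  ann <- read.delim(annotation, colClasses = c("character", "character", "logical"))
  need <- c("feature_id", "class", "is_calibrator")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(rownames(m), ann$feature_id)
  if (length(missing))
    stop("feature(s) missing from annotation: ", paste(head(missing, 5L), collapse = ", "))
  idx <- match(rownames(m), ann$feature_id)
  count_matrix(m, ann$class[idx], ann$is_calibrator[idx])
}

#' Write a count matrix (counts TSV plus feature annotation TSV)
#'
#' @param x a [count_matrix()].
#' @param path output counts TSV; the annotation goes to
#'   `<stem>_features.tsv` unless `annotation` is given.
#' @param annotation optional annotation path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, annotation = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(annotation))
    annotation <- paste0(sub("\\.(tsv|txt)$", "", path), "_features.tsv")
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(feature_id = rownames(x$counts),
                    class = unname(x$feature_class),
                    is_calibrator = unname(x$is_calibrator))
  write.table(ann, annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a CSV with at least `sample_id` and `compartment`; recognised
#' optional columns are `patient_id`, `cohort`, `sample_age`, `hbv`,
#' `cirrhosis`, `surgery`, `survival_time_months`, `event`.  Empty strings
#' become `NA`; clinical values are never imputed.  Compartment, cohort and
#' surgery levels are closed sets and anything else is an error.
#'
#' @param path CSV file.
#' @return A `data.frame`, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, colClasses = "character", na.strings = c("", "NA"))
  if (!all(c("sample_id", "compartment") %in% names(md)))
    stop("metadata must have sample_id and compartment columns")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  validate_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad))
      stop("unknown ", what, ": ", paste(bad, collapse = ", "),
           " (allowed: ", paste(levels, collapse = ", "), ")")
  }
  validate_levels(md$compartment, COMPARTMENTS, "compartment")
  if (anyNA(md$compartment)) stop("compartment is required for every sample")
  if ("cohort" %in% names(md)) validate_levels(md$cohort, COHORTS, "cohort")
  if ("surgery" %in% names(md))
    validate_levels(md$surgery, c("resection", "transplantation"), "surgery")
  for (col in c("sample_age", "survival_time_months"))
    if (col %in% names(md)) md[[col]] <- as.numeric(md[[col]])
  for (col in c("hbv", "cirrhosis", "event"))
    if (col %in% names(md)) md[[col]] <- as.logical(md[[col]])
  if ("survival_time_months" %in% names(md)) {
    st <- md$survival_time_months
    if (any(st < 0, na.rm = TRUE)) stop("survival_time_months must be >= 0")
  }
  md
}

#' Write sample metadata
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a miRNA-target table
#'
#' TSV with columns `mirna_id`, `gene_id`, `weighted_context_score` (the
#' predicted-repression efficacy score; more negative means stronger
#' predicted repression).  Duplicate (mirna, gene) rows or non-finite
#' scores are errors.
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_targets <- function(path) {
  tt <- read.delim(path, colClasses = c("character", "character", "numeric"))
  need <- c("mirna_id", "gene_id", "weighted_context_score")
  if (!all(need %in% names(tt)))
    stop("target table must have columns: ", paste(need, collapse = ", "))
  validate_targets(tt[need])
}

validate_targets <- function(tt) {
  key <- paste(tt$mirna_id, tt$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (mirna_id, gene_id) pair(s): ",
         paste(head(sub("\r", "/", unique(key[duplicated(key)])), 5L), collapse = ", "))
  if (any(!is.finite(tt$weighted_context_score)))
    stop("weighted_context_score must be finite")
  tt
}

#' Write a miRNA-target table
#' @param targets data.frame with `mirna_id`, `gene_id`,
#'   `weighted_context_score`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  validate_targets(targets)
  write.table(targets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file.
#' @return Named list of character vectors of members; the description is
#'   kept in a `description` attribute on each set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line needs name, description and >= 1 member: ", substr(l, 1, 40))
    structure(unique(parts[-(1:2)]), description = parts[2L])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% ""
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a differential expression result table
#'
#' TSV with columns `feature`, `logFC`, `aveExpr`, `t`, `p`, `adj_p`.
#'
#' @param de data.frame as returned by [run_contrast()].
#' @param path file path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_de <- function(de, path) {
  cols <- c("feature", "logFC", "aveExpr", "t", "p", "adj_p")
  stopifnot(all(cols %in% names(de)))
  write.table(de[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de
#' @export
read_de <- function(path) {
  de <- read.delim(path, colClasses = c("character", rep("numeric", 5L)))
  cols <- c("feature", "logFC", "aveExpr", "t", "p", "adj_p")
  if (!all(cols %in% names(de)))
    stop("DE table must have columns: ", paste(cols, collapse = ", "))
  de
}

#' Write / read an expression matrix as TSV
#'
#' The scale tag is stored in the name of the first column
#' (`feature_id.<scale>`), so a round trip preserves it.
#'
#' @param x an [expr_matrix()].
#' @param path file path.
#' @return `path` (writer) or an `expr_matrix` (reader).
#' @export
write_expr <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(id = rownames(x$E), x$E, check.names = FALSE)
  names(df)[1L] <- paste0("feature_id.", x$scale)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr
#' @export
read_expr <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  tag <- names(df)[1L]
  if (!grepl("^feature_id\\.", tag))
    stop("expression TSV must start with a feature_id.<scale> column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  expr_matrix(m, scale = sub("^feature_id\\.", "", tag))
}
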