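# Core domain types (S3) and delimited-text readers/writers for expression,
# clinical and gene-group annotation data, plus sample alignment.

#' Construct an expression matrix
#'
#' Wraps a numeric genes x samples matrix with validated, unique gene and
#' sample identifiers.  Values are assumed to be on a log-like scale; the
#' package never transforms them.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids)
#' @return an object of class `ExpressionMatrix` with fields `gene_ids`,
#'   `sample_ids` and `values`
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample ids in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  }
  structure(
    list(gene_ids = rownames(values), sample_ids = colnames(values), values = values),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Construct a survival response
#'
#' Holds the possibly right-censored follow-up time t_i (in years) and the
#' event indicator delta_i (1 = event observed, 0 = censored) per sample.
#'
#' @param sample_ids character vector of unique sample ids
#' @param time positive numeric follow-up times
#' @param event 0/1 event indicators
#' @return an object of class `SurvivalResponse`
#' @export
survival_response <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids", call. = FALSE)
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids)) {
    stop("time, event and sample_ids must have equal length", call. = FALSE)
  }
  if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be finite and strictly positive", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicator must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  structure(
    list(sample_ids = sample_ids, time = as.numeric(time), event = as.integer(event)),
    class = "SurvivalResponse"
  )
}

#' @export
print.SurvivalResponse <- function(x, ...) {
  cat(sprintf("SurvivalResponse: %d samples, %d events (%.1f%%)\n",
              length(x$time), sum(x$event), 100 * mean(x$event)))
  invisible(x)
}

#' Construct a clinical covariate block
#'
#' Numeric samples x q matrix of (already encoded) clinical covariates.  q may
#' be zero.  Clinical covariates enter Cox models as unpenalized mandatory
#' variables.
#'
#' @param sample_ids character vector of unique sample ids
#' @param values numeric samples x q matrix (q >= 0) with colnames
#' @param encoding optional list describing how categorical inputs were encoded
#' @return an object of class `ClinicalCovariates`
#' @export
clinical_covariates <- function(sample_ids, values, encoding = list()) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids", call. = FALSE)
  if (is.null(values)) values <- matrix(0, nrow = length(sample_ids), ncol = 0L)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("clinical values must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) != length(sample_ids)) {
    stop("clinical matrix row count must match sample_ids", call. = FALSE)
  }
  if (ncol(values) > 0L && is.null(colnames(values))) {
    stop("clinical matrix needs covariate colnames", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("clinical covariates contain missing values", call. = FALSE)
  rownames(values) <- sample_ids
  structure(
    list(sample_ids = sample_ids, covariate_names = colnames(values) %||% character(0),
         values = values, encoding = encoding),
    class = "ClinicalCovariates"
  )
}

#' Construct a gene-to-group annotation map
#'
#' Many-to-many mapping from group ids (for example GO biological-process
#' identifiers) to member gene ids.  Duplicate memberships collapse; member
#' lists are kept sorted for determinism.
#'
#' @param mapping named list; names are group ids, elements are character
#'   vectors of gene ids
#' @return an object of class `GeneGroupMap`
#' @export
gene_group_map <- function(mapping) {
  if (!is.list(mapping) || is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("mapping must be a named list of gene id vectors", call. = FALSE)
  }
  if (anyDuplicated(names(mapping))) stop("duplicated group ids", call. = FALSE)
  mapping <- lapply(mapping, function(g) sort(unique(as.character(g))))
  if (any(lengths(mapping) == 0L)) stop("groups with zero genes are not allowed", call. = FALSE)
  structure(mapping, class = "GeneGroupMap")
}

#' @export
print.GeneGroupMap <- function(x, ...) {
  cat(sprintf("GeneGroupMap: %d groups, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' First column holds gene ids, header row holds sample ids.  Missing or
#' non-numeric cells are rejected by default; `missing = "impute_mean"`
#' replaces missing cells by the gene's mean over observed samples (genes
#' with no observed value still error).
#'
#' @param path file path
#' @param sep field separator; `"\t"` for TSV (default), `","` for CSV
#' @param missing `"error"` (default) or `"impute_mean"`
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path, sep = "\t", missing = c("error", "impute_mean")) {
  missing <- match.arg(missing)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character", quote = "\"", comment.char = ""),
    error = function(e) stop("failed to parse expression file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(raw) < 2L) stop("expression file needs a gene id column plus >= 1 sample", call. = FALSE)
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop("duplicated gene id(s) in expression file: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (missing == "impute_mean" && anyNA(num)) {
    means <- rowMeans(num, na.rm = TRUE)
    idx <- which(is.na(num), arr.ind = TRUE)
    num[idx] <- means[idx[, 1L]]
    warning("imputed ", nrow(idx), " missing expression value(s) by per-gene means",
            call. = FALSE)
  }
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing expression value at gene '%s', sample '%s' (line %d)",
                 gene_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]], bad[1L, 1L] + 1L),
         call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  expression_matrix(num)
}

#' Write an expression matrix to delimited text
#'
#' @param expr an [expression_matrix()]
#' @param path output file path
#' @param sep field separator
#' @return `path`, invisibly
#' @export
write_expression <- function(expr, path, sep = "\t") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(gene_id = expr$gene_ids, expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic dummy coding: sorted levels, first level dropped
encode_clinical_column <- function(x, name) {
  if (is.numeric(x) && !anyNA(suppressWarnings(as.numeric(x)))) {
    return(list(values = matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, name)),
                encoding = list(type = "numeric")))
  }
  x_num <- suppressWarnings(as.numeric(x))
  if (!anyNA(x_num)) {
    return(list(values = matrix(x_num, ncol = 1L, dimnames = list(NULL, name)),
                encoding = list(type = "numeric")))
  }
  lev <- sort(unique(as.character(x)))
  if (length(lev) < 2L) {
    return(list(values = matrix(numeric(0), nrow = length(x), ncol = 0L), # constant column: no information
                encoding = list(type = "constant", levels = lev)))
  }
  keep <- lev[-1L]
  m <- vapply(keep, function(l) as.numeric(x == l), numeric(length(x)))
  m <- matrix(m, ncol = length(keep), dimnames = list(NULL, paste0(name, keep)))
  list(values = m, encoding = list(type = "dummy", levels = lev, dropped = lev[1L]))
}

#' Read survival response and clinical covariates from a CSV table
#'
#' The first column (or `id_col`) identifies samples.  Categorical covariates
#' are dummy-encoded deterministically: levels sorted, first level dropped.
#'
#' @param path CSV file path
#' @param time_col name of the positive follow-up time column (years)
#' @param event_col name of the 0/1 event indicator column
#' @param covariate_cols character vector of clinical covariate column names
#'   (may be empty)
#' @param id_col sample id column; defaults to the first column
#' @param sep field separator (default `","`)
#' @return list with components `survival` ([survival_response()]) and
#'   `clinical` ([clinical_covariates()])
#' @export
read_clinical <- function(path, time_col, event_col, covariate_cols = character(0),
                          id_col = NULL, sep = ",") {
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"", comment.char = ""),
    error = function(e) stop("failed to parse clinical file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  id_col <- id_col %||% names(raw)[1L]
  need <- c(id_col, time_col, event_col, covariate_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("clinical file lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- as.character(raw[[id_col]])
  time <- suppressWarnings(as.numeric(raw[[time_col]]))
  if (anyNA(time) || any(time <= 0)) {
    bad <- which(is.na(time) | time <= 0)[1L]
    stop(sprintf("invalid survival time in row %d (must be a positive number)", bad),
         call. = FALSE)
  }
  event_raw <- raw[[event_col]]
  if (!all(event_raw %in% c(0, 1, "0", "1"))) {
    stop("event column must contain only 0 and 1", call. = FALSE)
  }
  event <- as.integer(as.character(event_raw))
  surv <- survival_response(ids, time, event)

  blocks <- lapply(covariate_cols, function(cc) encode_clinical_column(raw[[cc]], cc))
  values <- do.call(cbind, c(list(matrix(0, nrow = length(ids), ncol = 0L)),
                             lapply(blocks, `[[`, "values")))
  encoding <- stats::setNames(lapply(blocks, `[[`, "encoding"), covariate_cols)
  clin <- clinical_covariates(ids, values, encoding)
  list(survival = surv, clinical = clin)
}

#' Write survival response and clinical covariates to CSV
#'
#' Inverse of [read_clinical()] for already-numeric covariates.
#'
#' @param survival a [survival_response()]
#' @param clinical a [clinical_covariates()] aligned to the same samples
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_clinical <- function(survival, clinical, path) {
  stopifnot(inherits(survival, "SurvivalResponse"), inherits(clinical, "ClinicalCovariates"))
  stopifnot(identical(survival$sample_ids, clinical$sample_ids))
  df <- data.frame(sample_id = survival$sample_ids, time = survival$time,
                   event = survival$event, check.names = FALSE)
  if (ncol(clinical$values) > 0L) df <- cbind(df, as.data.frame(clinical$values))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene-to-group annotation file
#'
#' Plain delimited text, one `gene_id<sep>group_id` pair per row, duplicates
#' allowed (collapsed on read).  A header row is detected and skipped when the
#' first line equals `gene_id<sep>group_id`.
#'
#' @param path file path
#' @param sep field separator (default tab)
#' @return a [gene_group_map()]
#' @export
read_group_map <- function(path, sep = "\t") {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = sep, stringsAsFactors = FALSE,
                      quote = "\"", comment.char = "", colClasses = "character"),
    error = function(e) stop("failed to parse group map '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L) stop("empty group map file", call. = FALSE)
  if (ncol(raw) != 2L) stop("group map must have exactly two columns (gene_id, group_id)",
                            call. = FALSE)
  if (identical(tolower(unlist(raw[1L, ])), c("gene_id", "group_id"))) {
    raw <- raw[-1L, , drop = FALSE]
    if (nrow(raw) == 0L) stop("empty group map file", call. = FALSE)
  }
  split_map <- split(raw[[1L]], raw[[2L]])
  gene_group_map(split_map)
}

#' Write a gene-to-group map as two-column TSV
#'
#' @param groups a [gene_group_map()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_group_map <- function(groups, path) {
  stopifnot(inherits(groups, "GeneGroupMap"))
  df <- data.frame(
    gene_id = unlist(unname(groups), use.names = FALSE),
    group_id = rep(names(groups), lengths(groups))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble an aligned analysis dataset
#'
#' Restricts all components to the ordered intersection of sample ids (order of
#' the expression matrix wins), intersects group membership with available
#' genes (dropping empty groups with a warning), and optionally restricts the
#' expression matrix to genes annotated to at least one group so that models
#' with different covariate types see the same genes.
#'
#' @param expression an [expression_matrix()]
#' @param survival a [survival_response()]
#' @param clinical a [clinical_covariates()], or `NULL` for none
#' @param groups a [gene_group_map()], or `NULL` for none
#' @param restrict_genes `"annotated"` (default) keeps only genes annotated to
#'   >= 1 group when a group map is present; `"none"` keeps all genes
#' @return an object of class `Dataset` with aligned components and the common
#'   `sample_ids`
#' @export
assemble_dataset <- function(expression, survival, clinical = NULL, groups = NULL,
                             restrict_genes = c("annotated", "none")) {
  restrict_genes <- match.arg(restrict_genes)
  stopifnot(inherits(expression, "ExpressionMatrix"), inherits(survival, "SurvivalResponse"))
  if (is.null(clinical)) {
    clinical <- clinical_covariates(survival$sample_ids,
                                    matrix(0, length(survival$sample_ids), 0L))
  }
  stopifnot(inherits(clinical, "ClinicalCovariates"))

  samples <- expression$sample_ids
  samples <- samples[samples %in% survival$sample_ids & samples %in% clinical$sample_ids]
  if (length(samples) == 0L) stop("no samples shared by expression and clinical tables",
                                  call. = FALSE)
  si <- match(samples, survival$sample_ids)
  surv <- survival_response(samples, survival$time[si], survival$event[si])
  ci <- match(samples, clinical$sample_ids)
  clin <- clinical_covariates(samples, clinical$values[ci, , drop = FALSE], clinical$encoding)

  expr_vals <- expression$values[, samples, drop = FALSE]
  if (!is.null(groups)) {
    stopifnot(inherits(groups, "GeneGroupMap"))
    trimmed <- lapply(groups, function(g) intersect(g, rownames(expr_vals)))
    empty <- names(trimmed)[lengths(trimmed) == 0L]
    if (length(empty) > 0L) {
      warning("dropping ", length(empty), " group(s) with no genes in the expression matrix: ",
              paste(utils::head(empty, 5L), collapse = ", "),
              if (length(empty) > 5L) ", ..." else "", call. = FALSE)
      trimmed <- trimmed[lengths(trimmed) > 0L]
    }
    if (length(trimmed) == 0L) stop("no group has genes in the expression matrix", call. = FALSE)
    groups <- gene_group_map(trimmed)
    if (restrict_genes == "annotated") {
      annotated <- unique(unlist(groups))
      expr_vals <- expr_vals[rownames(expr_vals) %in% annotated, , drop = FALSE]
    }
  }
  expr <- expression_matrix(expr_vals)
  structure(
    list(expression = expr, survival = surv, clinical = clin, groups = groups,
         sample_ids = samples),
    class = "Dataset"
  )
}

#' @export
print.Dataset <- function(x, ...) {
  cat(sprintf("Dataset: %d samples, %d genes, %d clinical covariates, %s groups\n",
              length(x$sample_ids), length(x$expression$gene_ids),
              ncol(x$clinical$values),
              if (is.null(x$groups)) "no" else length(x$groups)))
  invisible(x)
}

#' Restrict a dataset to a subset of samples
#'
#' Keeps the given samples in the stated order; used by the evaluation harness
#' to carve out training data so that no test-set information can reach
#' training-side computations.
#'
#' @param dataset a `Dataset`
#' @param sample_ids character vector, subset of `dataset$sample_ids`
#' @return a `Dataset` restricted to `sample_ids`
#' @export
subset_dataset <- function(dataset, sample_ids) {
  stopifnot(inherits(dataset, "Dataset"))
  sample_ids <- as.character(sample_ids)
  if (!all(sample_ids %in% dataset$sample_ids)) {
    stop("unknown sample id(s) in subset", call. = FALSE)
  }
  si <- match(sample_ids, dataset$survival$sample_ids)
  structure(
    list(
      expression = expression_matrix(dataset$expression$values[, sample_ids, drop = FALSE]),
      survival = survival_response(sample_ids, dataset$survival$time[si],
                                   dataset$survival$event[si]),
      clinical = clinical_covariates(
        sample_ids,
        dataset$clinical$values[match(sample_ids, dataset$clinical$sample_ids), , drop = FALSE],
        dataset$clinical$encoding),
      groups = dataset$groups,
      sample_ids = sample_ids
    ),
    class = "Dataset"
  )
}
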