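# Genomic design construction: genes, whole groups, or preclustered
# subclusters as covariates, with gene sets summarized by the first principal
# component of their standardized expression.  All transform constants
# (per-gene center/scale, PC loadings, covariate center/scale) are learned on
# the training samples and frozen, so test samples can be projected without
# refitting anything.

#' First principal component of a gene set
#'
#' Genes are standardized (mean 0, unit variance across the provided samples;
#' correlation-scale PCA, consistent with the correlation-based clustering)
#' and the per-sample scores of the first right singular vector are returned.
#' The sign of a principal component is arbitrary; scores are oriented to
#' correlate positively with a reference profile -- the standardized medoid
#' gene when one is available, otherwise the mean standardized member profile.
#'
#' @param expr_subset an [expression_matrix()] (or genes x samples matrix with
#'   rownames) restricted to one gene set; >= 1 gene, >= 2 samples
#' @param reference_gene gene id used for sign orientation, or `NULL` to use
#'   the mean member profile
#' @return list with `scores` (named per sample), `loadings` (unit-norm, named
#'   per retained gene), `center`, `scale` (per retained gene) and `genes`
#' @export
first_principal_component <- function(expr_subset, reference_gene = NULL) {
  vals <- if (inherits(expr_subset, "ExpressionMatrix")) expr_subset$values else expr_subset
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1L, dimnames = list("gene", names(vals)))
  if (is.null(rownames(vals))) stop("need gene rownames", call. = FALSE)
  if (ncol(vals) < 2L) stop("need at least 2 samples", call. = FALSE)

  ctr <- rowMeans(vals)
  scl <- apply(vals, 1L, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance gene(s) from principal component",
            call. = FALSE)
  }
  if (!any(keep)) stop("all genes in the set have zero variance", call. = FALSE)
  vals <- vals[keep, , drop = FALSE]
  ctr <- ctr[keep]
  scl <- scl[keep]
  Xs <- (vals - ctr) / scl                       # standardized genes x samples
  M <- t(Xs)                                     # samples x genes
  sv <- svd(M, nu = 0L, nv = 1L)
  loadings <- drop(sv$v[, 1L])
  scores <- drop(M %*% loadings)

  ref <- if (!is.null(reference_gene) && reference_gene %in% rownames(vals)) {
    Xs[reference_gene, ]
  } else {
    colMeans(Xs)
  }
  s <- sum(scores * (ref - mean(ref)))           # sign of covariance with reference
  if (s == 0) s <- if (loadings[which(loadings != 0)[1L]] >= 0) 1 else -1
  if (s < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  names(scores) <- colnames(vals)
  names(loadings) <- rownames(vals)
  list(scores = scores, loadings = loadings, center = ctr, scale = scl,
       genes = rownames(vals))
}

# one covariate's frozen transform: genes, per-gene center/scale, loadings,
# and the train-set score center/scale applied on top
make_covariate <- function(id, group_id, genes, medoid, pc) {
  scores <- pc$scores
  sc <- mean(scores)
  ss <- stats::sd(scores)
  if (!is.finite(ss) || ss == 0) ss <- 1
  list(covariate_id = id, group_id = group_id, genes = genes,
       medoid = medoid, loadings = pc$loadings, center = pc$center,
       scale = pc$scale, score_center = sc, score_scale = ss,
       values = (scores - sc) / ss)
}

#' Build a genomic design matrix
#'
#' Turns the dataset's genes, groups, or preclustered subclusters into a
#' samples x covariates matrix.  Every covariate is standardized to mean 0 and
#' unit variance on the training samples (penalties are scale-sensitive), and
#' all constants are stored so [project_design()] can transform unseen
#' samples.
#'
#' @param dataset a `Dataset`
#' @param mode `"genes"` (one covariate per gene), `"groups"` (first PC per
#'   group) or `"preclustered"` (first PC per (group, cluster) pair, oriented
#'   by the cluster medoid)
#' @param preclustered a [precluster_all_groups()] result; required for
#'   `mode = "preclustered"`
#' @param train_sample_ids samples used to learn all transform constants;
#'   default: all samples of `dataset`
#' @return an object of class `GenomicDesign` with fields `mode`,
#'   `sample_ids`, `X` (train samples x p standardized matrix),
#'   `covariate_ids` and `meta` (per-covariate provenance and transforms)
#' @export
build_design <- function(dataset, mode = c("genes", "groups", "preclustered"),
                         preclustered = NULL, train_sample_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "Dataset"))
  train_sample_ids <- train_sample_ids %||% dataset$sample_ids
  if (!all(train_sample_ids %in% dataset$sample_ids)) {
    stop("train_sample_ids must be a subset of dataset samples", call. = FALSE)
  }
  expr <- dataset$expression$values[, train_sample_ids, drop = FALSE]

  covs <- list()
  if (mode == "genes") {
    sds <- apply(expr, 1L, stats::sd)
    genes <- rownames(expr)[sds > 0]
    if (length(genes) < length(sds)) {
      warning("dropping ", length(sds) - length(genes),
              " zero-variance gene(s) from the design", call. = FALSE)
    }
    covs <- lapply(genes, function(g) {
      pc <- first_principal_component(expr[g, , drop = FALSE], reference_gene = g)
      make_covariate(g, NA_character_, g, NA_character_, pc)
    })
  } else {
    if (is.null(dataset$groups)) stop("dataset has no gene groups", call. = FALSE)
    if (mode == "preclustered") {
      if (!inherits(preclustered, "PreclusteredGroups")) {
        stop("mode 'preclustered' requires a PreclusteredGroups object", call. = FALSE)
      }
      for (gid in names(preclustered)) {
        g <- preclustered[[gid]]
        for (k in seq_along(g$clusters)) {
          cl <- g$clusters[[k]]
          genes <- intersect(cl$members, rownames(expr))
          if (length(genes) == 0L) next
          pc <- tryCatch(
            first_principal_component(expr[genes, , drop = FALSE],
                                      reference_gene = cl$medoid),
            error = function(e) NULL)
          if (is.null(pc)) next                  # all-flat cluster: no covariate
          covs[[length(covs) + 1L]] <-
            make_covariate(sprintf("%s.c%d", gid, k), gid, genes, cl$medoid, pc)
        }
      }
    } else {
      for (gid in names(dataset$groups)) {
        genes <- intersect(dataset$groups[[gid]], rownames(expr))
        if (length(genes) == 0L) next
        pc <- tryCatch(
          first_principal_component(expr[genes, , drop = FALSE], reference_gene = NULL),
          error = function(e) NULL)
        if (is.null(pc)) next
        covs[[length(covs) + 1L]] <- make_covariate(gid, gid, genes, NA_character_, pc)
      }
    }
  }
  if (length(covs) == 0L) stop("no usable covariates for mode '", mode, "'", call. = FALSE)

  X <- vapply(covs, `[[`, numeric(length(train_sample_ids)), "values")
  X <- matrix(X, nrow = length(train_sample_ids),
              dimnames = list(train_sample_ids,
                              vapply(covs, `[[`, character(1), "covariate_id")))
  meta <- lapply(covs, function(cv) cv[setdiff(names(cv), "values")])
  structure(
    list(mode = mode, sample_ids = train_sample_ids, X = X,
         covariate_ids = colnames(X), meta = meta),
    class = "GenomicDesign"
  )
}

#' @export
print.GenomicDesign <- function(x, ...) {
  cat(sprintf("GenomicDesign: mode '%s', %d samples x %d covariates\n",
              x$mode, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Project new samples onto a fitted design
#'
#' Applies the stored per-gene standardization, PC loadings and covariate
#' standardization of a training design to new samples.  Nothing is refitted,
#' so test-set information cannot leak into the model.
#'
#' @param design a [build_design()] result
#' @param dataset a `Dataset` containing the samples to project
#' @param sample_ids samples to transform
#' @return a `length(sample_ids)` x p covariate matrix
#' @export
project_design <- function(design, dataset, sample_ids) {
  stopifnot(inherits(design, "GenomicDesign"), inherits(dataset, "Dataset"))
  if (!all(sample_ids %in% dataset$sample_ids)) {
    stop("unknown sample id(s) to project", call. = FALSE)
  }
  expr <- dataset$expression$values
  X <- matrix(NA_real_, nrow = length(sample_ids), ncol = length(design$meta),
              dimnames = list(sample_ids, design$covariate_ids))
  for (j in seq_along(design$meta)) {
    m <- design$meta[[j]]
    genes <- names(m$loadings)
    if (!all(genes %in% rownames(expr))) {
      stop("gene(s) required by covariate '", m$covariate_id,
           "' missing from dataset", call. = FALSE)
    }
    sub <- expr[genes, sample_ids, drop = FALSE]
    Xs <- (sub - m$center) / m$scale
    scores <- drop(t(Xs) %*% m$loadings)
    X[, j] <- (scores - m$score_center) / m$score_scale
  }
  X
}

#' Serialize a design matrix and its metadata to TSV
#'
#' @param design a [build_design()] result
#' @param matrix_path output TSV for the samples x covariates matrix
#' @param meta_path output TSV for per-covariate provenance
#' @return invisibly, a list with both paths
#' @export
write_design <- function(design, matrix_path, meta_path) {
  stopifnot(inherits(design, "GenomicDesign"))
  df <- data.frame(sample_id = rownames(design$X), design$X, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- do.call(rbind, lapply(design$meta, function(m) {
    data.frame(covariate_id = m$covariate_id, group_id = m$group_id,
               medoid = m$medoid, n_genes = length(m$genes),
               genes = paste(m$genes, collapse = ","))
  }))
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(matrix = matrix_path, meta = meta_path))
}
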