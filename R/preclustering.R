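# Preclustering of gene groups: PAM on the 1 - Pearson-correlation
# dissimilarity, with the number of clusters K chosen by maximum mean
# intra-cluster correlation (ICC).
#
# The PAM implementation is deliberately self-contained and deterministic:
# classic greedy build phase followed by steepest-descent swap phase, all ties
# broken toward the lowest gene index.  This makes the clustering reproducible
# across platforms and lets the test suite compare the objective against
# exhaustive enumeration on small instances.

#' Correlation-based dissimilarity matrix for a set of genes
#'
#' d(i, j) = 1 - Cor(x_i, x_j) with Pearson correlation computed across
#' samples.  Positively correlated genes are close (d near 0), anti-correlated
#' genes are far apart (d near 2).  Zero-variance genes have undefined
#' correlation; they are treated as uncorrelated with everything (Cor = 0,
#' hence d = 1), which marks flat profiles as uninformative without failing.
#'
#' @param expr_subset an [expression_matrix()] restricted to the genes of one
#'   group (>= 2 genes, >= 3 samples), or a plain genes x samples matrix with
#'   rownames
#' @return an object of class `DissimilarityMatrix`: list with `gene_ids` and
#'   the symmetric matrix `d` (zero diagonal, entries in \[0, 2\])
#' @export
correlation_dissimilarity <- function(expr_subset) {
  vals <- if (inherits(expr_subset, "ExpressionMatrix")) expr_subset$values else expr_subset
  if (!is.matrix(vals) || is.null(rownames(vals))) {
    stop("need a genes x samples matrix with gene rownames", call. = FALSE)
  }
  if (nrow(vals) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(vals) < 3L) stop("need at least 3 samples for a stable correlation", call. = FALSE)
  sds <- apply(vals, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(vals)))
  cc[!is.finite(cc)] <- 0          # zero-variance genes: define Cor = 0
  diag(cc) <- 1
  d <- 1 - cc
  d <- pmin(pmax(d, 0), 2)         # clamp numerical noise
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(vals), rownames(vals))
  structure(list(gene_ids = rownames(vals), d = d, zero_variance = rownames(vals)[sds == 0]),
            class = "DissimilarityMatrix")
}

# total cost of a medoid set: sum over genes of min dissimilarity to a medoid
pam_objective <- function(d, medoid_idx) {
  sum(apply(d[, medoid_idx, drop = FALSE], 1L, min))
}

# nearest-medoid labels, ties to the medoid with the lowest index
pam_labels <- function(d, medoid_idx) {
  sub <- d[, medoid_idx, drop = FALSE]
  apply(sub, 1L, which.min)        # which.min takes the first (lowest) on ties
}

#' Partitioning around medoids on a precomputed dissimilarity
#'
#' Minimizes the sum over genes of the dissimilarity to the closest of K
#' medoid genes.  Small instances (at most `exhaustive_limit` candidate medoid
#' sets) are solved exactly by enumeration; larger instances use the classic
#' PAM heuristic -- a greedy build phase (first medoid minimizes total
#' dissimilarity, each further medoid gives the largest objective decrease)
#' followed by a steepest-descent swap phase that repeatedly applies the best
#' improving (medoid, non-medoid) exchange until no swap improves.
#' Deterministic: all ties break toward the lowest gene index
#' (lexicographically smallest medoid set under enumeration).
#'
#' @param dissim a [correlation_dissimilarity()] result (or any object with
#'   fields `gene_ids` and symmetric matrix `d`)
#' @param K number of clusters, 1 <= K <= number of genes
#' @param exhaustive_limit maximum number of medoid subsets to enumerate
#'   exactly before falling back to build + swap (default 2000)
#' @return an object of class `ClusterAssignment`: `K`, `medoid_ids`, `labels`
#'   (per-gene cluster index in 1..K, named by gene), `objective`, and -- once
#'   filled in by [select_k()] -- `per_cluster_icc` and `mean_icc`
#' @export
pam_cluster <- function(dissim, K, exhaustive_limit = 2000L) {
  d <- dissim$d
  N <- nrow(d)
  if (!is_scalar_number(K) || K != round(K)) stop("K must be an integer", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > N) stop("K must not exceed the number of genes (", N, ")", call. = FALSE)

  if (choose(N, K) <= exhaustive_limit) {
    combs <- utils::combn(N, K)
    dmin <- d[, combs[1L, ], drop = FALSE]       # N x n_combs running minimum
    for (k in seq_len(K)[-1L]) dmin <- pmin(dmin, d[, combs[k, ], drop = FALSE])
    medoids <- combs[, which.min(colSums(dmin))] # ties: lexicographically first set
    return(finish_pam(dissim, d, K, medoids))
  }

  # build phase
  medoids <- which.min(colSums(d))
  if (K > 1L) {
    dmin <- d[, medoids]                     # current distance to closest medoid
    for (k in 2L:K) {
      cand <- setdiff(seq_len(N), medoids)
      # decrease of objective when adding candidate c: sum_i max(dmin_i - d_ic, 0)
      gains <- vapply(cand, function(cc) sum(pmax(dmin - d[, cc], 0)), numeric(1))
      best <- cand[which.max(gains)]         # ties: lowest index via which.max
      medoids <- c(medoids, best)
      dmin <- pmin(dmin, d[, best])
    }
  }

  # swap phase: steepest descent
  obj <- pam_objective(d, medoids)
  repeat {
    best_obj <- obj
    best_swap <- NULL
    non_medoids <- setdiff(seq_len(N), medoids)
    for (mi in seq_along(medoids)) {
      for (h in non_medoids) {
        cand_set <- medoids
        cand_set[mi] <- h
        o <- pam_objective(d, cand_set)
        if (o < best_obj - 1e-12) {
          best_obj <- o
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
    obj <- best_obj
  }
  finish_pam(dissim, d, K, medoids)
}

finish_pam <- function(dissim, d, K, medoids) {
  medoids <- sort(medoids)
  labels <- pam_labels(d, medoids)
  labels[medoids] <- seq_len(K)    # a medoid always belongs to its own cluster,
                                   # even under duplicated profiles (d = 0 ties)
  names(labels) <- dissim$gene_ids
  structure(
    list(K = K, medoid_ids = dissim$gene_ids[medoids], medoid_idx = medoids,
         labels = labels, objective = pam_objective(d, medoids),
         per_cluster_icc = NULL, mean_icc = NA_real_),
    class = "ClusterAssignment"
  )
}

#' Intra-cluster correlation of one cluster
#'
#' Mean of the strictly-lower-triangle entries of the within-cluster
#' correlation matrix, ICC = 2 / (n (n - 1)) * sum of pairwise correlations
#' for a cluster of n genes.  Singleton clusters contribute no pairwise
#' evidence and return 0 by convention, which penalizes fragmenting groups
#' into singletons during K selection.
#'
#' @param cor_sub correlation matrix restricted to the genes of one cluster
#' @return a number in \[-1, 1\]
#' @export
intra_cluster_correlation <- function(cor_sub) {
  if (is.null(dim(cor_sub))) cor_sub <- as.matrix(cor_sub)
  n <- nrow(cor_sub)
  if (n <= 1L) return(0)
  mean(cor_sub[lower.tri(cor_sub)])
}

# mean ICC over the clusters of an assignment
assignment_mean_icc <- function(assignment, cor_mat) {
  icc <- vapply(seq_len(assignment$K), function(k) {
    members <- which(assignment$labels == k)
    intra_cluster_correlation(cor_mat[members, members, drop = FALSE])
  }, numeric(1))
  list(per_cluster_icc = icc, mean_icc = mean(icc))
}

#' Choose the number of clusters by maximum mean intra-cluster correlation
#'
#' Runs PAM for each K in 2..min(N-1, k_max) and returns the assignment whose
#' clusters have the largest mean ICC; ties break toward the smaller K
#' (parsimony).
#'
#' @param dissim a [correlation_dissimilarity()] result for N >= 3 genes
#' @param cor_mat the corresponding N x N correlation matrix (1 - `dissim$d`)
#' @param k_max largest K to consider; use N - 1 for the full sweep
#' @return the selected `ClusterAssignment`, with `per_cluster_icc` and
#'   `mean_icc` filled in
#' @export
select_k <- function(dissim, cor_mat = NULL, k_max = 20L) {
  N <- length(dissim$gene_ids)
  if (N < 3L) stop("select_k requires >= 3 genes; tiny groups use a single cluster",
                   call. = FALSE)
  if (is.null(cor_mat)) cor_mat <- 1 - dissim$d
  ks <- 2L:min(N - 1L, as.integer(k_max))
  best <- NULL
  for (K in ks) {
    a <- pam_cluster(dissim, K)
    icc <- assignment_mean_icc(a, cor_mat)
    a$per_cluster_icc <- icc$per_cluster_icc
    a$mean_icc <- icc$mean_icc
    if (is.null(best) || a$mean_icc > best$mean_icc + 1e-12) best <- a
  }
  best
}

# degenerate rule for groups of size 1-2: a single cluster whose medoid is the
# min-total-dissimilarity gene (ties lexicographic; for size 2 the totals are
# always equal, so the lexicographically smaller gene id wins)
single_cluster_assignment <- function(gene_ids, expr_vals) {
  n <- length(gene_ids)
  ord <- order(gene_ids)
  medoid <- gene_ids[ord[1L]]
  labels <- stats::setNames(rep(1L, n), gene_ids)
  icc <- if (n == 2L) {
    cc <- suppressWarnings(stats::cor(expr_vals[1L, ], expr_vals[2L, ]))
    if (!is.finite(cc)) 0 else cc
  } else 0
  structure(
    list(K = 1L, medoid_ids = medoid, medoid_idx = match(medoid, gene_ids),
         labels = labels, objective = NA_real_,
         per_cluster_icc = icc, mean_icc = icc),
    class = "ClusterAssignment"
  )
}

#' Precluster every gene group of a dataset
#'
#' For each group with >= 3 genes: computes the correlation dissimilarity of
#' the member genes and selects the PAM clustering with maximal mean ICC via
#' [select_k()].  Groups of size 1-2 become a single trivial cluster.  A gene
#' annotated to several groups is clustered independently within each group.
#'
#' @param dataset a `Dataset` with a group map; expression restricted to the
#'   samples preclustering may see (training samples, normally)
#' @param k_max largest K per group (default 20); set to `Inf` for the full
#'   K = 2..N-1 sweep
#' @return an object of class `PreclusteredGroups`: named list (one element
#'   per group) with fields `K`, `mean_icc`, `per_cluster_icc` and `clusters`
#'   (list of `list(members, medoid, size)`)
#' @export
precluster_all_groups <- function(dataset, k_max = 20L) {
  stopifnot(inherits(dataset, "Dataset"))
  if (is.null(dataset$groups) || length(dataset$groups) == 0L) {
    stop("dataset has no gene groups", call. = FALSE)
  }
  expr <- dataset$expression$values
  out <- lapply(names(dataset$groups), function(gid) {
    genes <- intersect(dataset$groups[[gid]], rownames(expr))
    sub <- expr[genes, , drop = FALSE]
    assignment <- if (length(genes) >= 3L) {
      dis <- correlation_dissimilarity(sub)
      select_k(dis, 1 - dis$d, k_max = k_max)
    } else {
      single_cluster_assignment(genes, sub)
    }
    clusters <- lapply(seq_len(assignment$K), function(k) {
      members <- sort(names(assignment$labels)[assignment$labels == k])
      list(members = members, medoid = assignment$medoid_ids[k], size = length(members))
    })
    list(group_id = gid, K = assignment$K, mean_icc = assignment$mean_icc,
         per_cluster_icc = assignment$per_cluster_icc, clusters = clusters,
         labels = assignment$labels)
  })
  names(out) <- names(dataset$groups)
  structure(out, class = "PreclusteredGroups")
}

#' @export
print.PreclusteredGroups <- function(x, ...) {
  ks <- vapply(x, `[[`, integer(1), "K")
  cat(sprintf("PreclusteredGroups: %d groups, %d clusters total (K range %d-%d)\n",
              length(x), sum(ks), min(ks), max(ks)))
  invisible(x)
}

#' Serialize preclustering results to TSV
#'
#' Writes a membership table (group_id, cluster_index, medoid_gene,
#' member_gene) and a per-group summary (group_id, N, K, mean_icc).
#'
#' @param preclustered a [precluster_all_groups()] result
#' @param members_path output TSV for cluster memberships
#' @param summary_path output TSV for the per-group summary
#' @return invisibly, a list with both paths
#' @export
write_preclustered_groups <- function(preclustered, members_path, summary_path) {
  stopifnot(inherits(preclustered, "PreclusteredGroups"))
  rows <- do.call(rbind, lapply(preclustered, function(g) {
    do.call(rbind, lapply(seq_along(g$clusters), function(k) {
      cl <- g$clusters[[k]]
      data.frame(group_id = g$group_id, cluster_index = k,
                 medoid_gene = cl$medoid, member_gene = cl$members)
    }))
  }))
  utils::write.table(rows, members_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- data.frame(
    group_id = vapply(preclustered, `[[`, character(1), "group_id"),
    N = vapply(preclustered, function(g) sum(vapply(g$clusters, `[[`, integer(1), "size")),
               integer(1)),
    K = vapply(preclustered, `[[`, integer(1), "K"),
    mean_icc = vapply(preclustered, `[[`, numeric(1), "mean_icc")
  )
  utils::write.table(summ, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(members = members_path, summary = summary_path))
}
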