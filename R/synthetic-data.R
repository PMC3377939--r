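# Synthetic data with the structure the method assumes: gene groups containing
# block-correlated subclusters, expression driven by per-cluster latent
# factors, and survival times from a Cox model on those factors with
# independent exponential censoring.  Ground truth is recorded so recovery
# can be tested end to end.

#' Simulate group/cluster membership structure
#'
#' Builds `n_groups` gene groups with sizes drawn uniformly from
#' `genes_per_group`, partitions each group into latent subclusters (cluster
#' count drawn from `clusters_per_group`, capped so clusters have >= 2 genes),
#' and optionally adds a fraction of genes to a second group to create
#' many-to-many annotation.
#'
#' @param n_groups number of groups
#' @param genes_per_group integer range `c(lo, hi)` of group sizes
#' @param clusters_per_group integer range `c(lo, hi)` of latent cluster
#'   counts per group
#' @param overlap_fraction fraction of genes additionally annotated to a
#'   second group (0 = disjoint groups)
#' @param seed integer seed
#' @return an object of class `SimulationStructure`: `groups`
#'   ([gene_group_map()]), `clusters` (cluster id -> member genes),
#'   `gene_cluster` (gene -> home cluster id), `group_clusters` (group ->
#'   cluster ids)
#' @export
simulate_structure <- function(n_groups, genes_per_group, clusters_per_group = c(2L, 3L),
                               overlap_fraction = 0, seed = 1L) {
  stopifnot(n_groups >= 1, all(genes_per_group >= 2), all(clusters_per_group >= 1))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  if (overlap_fraction > 0 && n_groups < 2L) {
    stop("overlap requires at least two groups", call. = FALSE)
  }
  set.seed(seed)
  genes_per_group <- rep(range(genes_per_group), length.out = 2L)
  clusters_per_group <- rep(range(clusters_per_group), length.out = 2L)
  sample_range <- function(lo, hi, n) {      # safe for lo == hi (no 1:x surprise)
    if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
  }
  sizes <- sample_range(genes_per_group[1L], genes_per_group[2L], n_groups)
  group_ids <- sprintf("GO:%04d", seq_len(n_groups))
  total <- sum(sizes)
  gene_ids <- sprintf("g%05d", seq_len(total))

  groups <- list()
  clusters <- list()
  gene_cluster <- character(0)
  group_clusters <- list()
  offset <- 0L
  for (i in seq_len(n_groups)) {
    members <- gene_ids[offset + seq_len(sizes[i])]
    offset <- offset + sizes[i]
    kmax <- max(1L, sizes[i] %/% 2L)
    k <- min(sample_range(clusters_per_group[1L], clusters_per_group[2L], 1L), kmax)
    lab <- sort(rep_len(seq_len(k), sizes[i]))
    cids <- sprintf("%s.t%d", group_ids[i], seq_len(k))
    for (j in seq_len(k)) {
      clusters[[cids[j]]] <- members[lab == j]
    }
    gene_cluster[members] <- cids[lab]
    groups[[group_ids[i]]] <- members
    group_clusters[[group_ids[i]]] <- cids
  }

  n_over <- round(overlap_fraction * total)
  if (n_over > 0L) {
    extra <- sample(gene_ids, n_over)
    home <- rep(names(groups), lengths(groups))[match(extra, unlist(groups))]
    for (idx in seq_along(extra)) {
      other <- sample(setdiff(names(groups), home[idx]), 1L)
      groups[[other]] <- c(groups[[other]], extra[idx])
    }
  }
  structure(
    list(groups = gene_group_map(groups), clusters = clusters,
         gene_cluster = gene_cluster, group_clusters = group_clusters,
         params = list(n_groups = n_groups, sizes = sizes,
                       overlap_fraction = overlap_fraction, seed = seed)),
    class = "SimulationStructure"
  )
}

#' Simulate expression driven by latent cluster factors
#'
#' Every latent cluster gets an independent standard-normal factor per sample;
#' a member gene is sqrt(rho) * factor + sqrt(1 - rho) * noise_sd * noise, so
#' with the default `noise_sd = 1` the expected within-cluster correlation is
#' `rho` and across-cluster correlations are ~0.  Genes listed in
#' `flip_genes` are negated, creating anti-correlated members.
#'
#' @param structure a [simulate_structure()] result
#' @param n_samples number of samples
#' @param within_cluster_rho target within-cluster correlation, 0 <= rho < 1
#' @param noise_sd standard deviation multiplier of the idiosyncratic noise
#' @param flip_genes character vector of gene ids whose profile is negated
#' @param seed integer seed
#' @return list with `expression` (an [expression_matrix()]) and `factors`
#'   (samples x clusters matrix of the latent factors)
#' @export
simulate_expression <- function(structure, n_samples, within_cluster_rho,
                                noise_sd = 1, flip_genes = character(0), seed = 1L) {
  stopifnot(inherits(structure, "SimulationStructure"))
  rho <- within_cluster_rho
  if (rho < 0 || rho >= 1) stop("within_cluster_rho must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  cids <- names(structure$clusters)
  Fm <- matrix(stats::rnorm(n_samples * length(cids)), nrow = n_samples,
               dimnames = list(sprintf("s%04d", seq_len(n_samples)), cids))
  genes <- names(structure$gene_cluster)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = n_samples,
                 dimnames = list(genes, rownames(Fm)))
  for (g in genes) {
    f <- Fm[, structure$gene_cluster[[g]]]
    x <- sqrt(rho) * f + sqrt(1 - rho) * noise_sd * stats::rnorm(n_samples)
    if (g %in% flip_genes) x <- -x
    vals[g, ] <- x
  }
  list(expression = expression_matrix(vals), factors = Fm)
}

#' Simulate survival times from a Cox model on latent factors
#'
#' Event times are exponential with rate baseline_rate * exp(beta' f + gamma'
#' z); censoring times are independent exponential with rate
#' `censoring_rate` (0 disables censoring).  Observed time is the minimum,
#' the event indicator marks which came first.
#'
#' @param factors samples x clusters latent factor matrix
#' @param true_beta named coefficient vector over (a subset of) the factor
#'   columns
#' @param Z clinical covariate matrix (or `NULL`)
#' @param true_gamma coefficients for `Z`
#' @param baseline_rate exponential baseline hazard rate (events per year)
#' @param censoring_rate exponential censoring hazard rate
#' @param seed integer seed
#' @return a [survival_response()] for the rownames of `factors`
#' @export
simulate_survival <- function(factors, true_beta = numeric(0), Z = NULL,
                              true_gamma = numeric(0), baseline_rate = 0.1,
                              censoring_rate = 0.1, seed = 1L) {
  stopifnot(baseline_rate > 0, censoring_rate >= 0)
  if (length(true_beta) > 0 && !all(names(true_beta) %in% colnames(factors))) {
    stop("true_beta names must be factor columns", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(factors)
  eta <- numeric(n)
  if (length(true_beta) > 0) {
    eta <- eta + drop(factors[, names(true_beta), drop = FALSE] %*% true_beta)
  }
  if (!is.null(Z) && length(true_gamma) > 0) {
    eta <- eta + drop(as.matrix(Z) %*% true_gamma)
  }
  T_ev <- stats::rexp(n, rate = baseline_rate * exp(eta))
  C <- if (censoring_rate > 0) stats::rexp(n, rate = censoring_rate) else rep(Inf, n)
  survival_response(rownames(factors), pmin(T_ev, C), as.integer(T_ev <= C))
}

# clinical covariates: one binary (e.g. high grade) and one standard-normal
# (e.g. standardized age) variable, exercising the unpenalized block
simulate_clinical <- function(sample_ids, seed) {
  set.seed(seed)
  n <- length(sample_ids)
  vals <- cbind(grade_high = stats::rbinom(n, 1L, 0.5),
                age_std = stats::rnorm(n))
  clinical_covariates(sample_ids, vals)
}

# hand-built structure used by the anticorrelated preset: each group has one
# small survival-relevant cluster and one large distractor cluster whose
# second half is sign-flipped
anticorrelated_structure <- function(n_groups = 6L, signal_size = 5L, distractor_size = 15L) {
  groups <- list()
  clusters <- list()
  gene_cluster <- character(0)
  group_clusters <- list()
  counter <- 0L
  flip <- character(0)
  for (i in seq_len(n_groups)) {
    gid <- sprintf("GO:%04d", i)
    members <- sprintf("g%05d", counter + seq_len(signal_size + distractor_size))
    counter <- counter + length(members)
    sig <- members[seq_len(signal_size)]
    dis <- members[signal_size + seq_len(distractor_size)]
    cs <- sprintf("%s.t%d", gid, 1:2)
    clusters[[cs[1L]]] <- sig
    clusters[[cs[2L]]] <- dis
    gene_cluster[sig] <- cs[1L]
    gene_cluster[dis] <- cs[2L]
    flip <- c(flip, dis[seq_len(distractor_size %/% 2L)])
    groups[[gid]] <- members
    group_clusters[[gid]] <- cs
  }
  list(structure = structure(
    list(groups = gene_group_map(groups), clusters = clusters,
         gene_cluster = gene_cluster, group_clusters = group_clusters,
         params = list(n_groups = n_groups, sizes = rep(signal_size + distractor_size, n_groups),
                       overlap_fraction = 0, seed = NA)),
    class = "SimulationStructure"
  ), flip_genes = flip)
}

#' Benchmark dataset presets
#'
#' Fixed simulation scenarios used throughout the test suite:
#' \describe{
#'   \item{tiny}{20 genes in 4 groups, 40 samples; one true cluster effect.
#'     Unit-test scale.}
#'   \item{null}{10 groups of 8 genes, 150 samples; no survival association
#'     at all (beta = gamma = 0).}
#'   \item{clustered_signal}{3 signal groups among 50 noise groups (12 genes,
#'     2 latent clusters each), n = 200, within-cluster correlation 0.8,
#'     cluster effects beta = (1, -1, 1), ~25\% events.}
#'   \item{anticorrelated}{6 groups of 20 genes, each a 5-gene
#'     survival-relevant cluster plus a 15-gene distractor cluster with half
#'     of its genes sign-flipped; n = 300, rho = 0.9.  Whole-group first PCs
#'     track the distractor factor, cluster-level first PCs recover the
#'     signal factor.}
#' }
#'
#' @param preset one of `"tiny"`, `"null"`, `"clustered_signal"`,
#'   `"anticorrelated"`
#' @param seed integer master seed; sub-seeds are derived per stage
#' @return list with `dataset` (a `Dataset`), `truth` (a `SimulationTruth`)
#'   and `factors` (latent factor matrix)
#' @export
make_benchmark_dataset <- function(preset = c("tiny", "null", "clustered_signal",
                                              "anticorrelated"), seed = 1L) {
  preset <- match.arg(preset)
  s <- function(k) derive_seed(seed, k)
  flip <- character(0)
  if (preset == "tiny") {
    str <- simulate_structure(4L, c(5L, 5L), c(2L, 2L), 0, seed = s(1))
    rho <- 0.7; n <- 40L
    true_beta <- c(1); names(true_beta) <- names(str$clusters)[1L]
    true_gamma <- c(grade_high = 0.5, age_std = 0.3)
    baseline_rate <- 0.08; censoring_rate <- 0.08
  } else if (preset == "null") {
    str <- simulate_structure(10L, c(8L, 8L), c(2L, 2L), 0, seed = s(1))
    rho <- 0.6; n <- 150L
    true_beta <- numeric(0)
    true_gamma <- c(grade_high = 0, age_std = 0)
    baseline_rate <- 0.08; censoring_rate <- 0.08
  } else if (preset == "clustered_signal") {
    str <- simulate_structure(53L, c(12L, 12L), c(2L, 2L), 0, seed = s(1))
    rho <- 0.8; n <- 200L
    signal_groups <- names(str$group_clusters)[1:3]
    signal_clusters <- vapply(str$group_clusters[signal_groups], `[[`, character(1), 1L)
    true_beta <- stats::setNames(c(1, -1, 1), signal_clusters)
    true_gamma <- c(grade_high = 0.5, age_std = 0.3)
    # ~25% events: P(event) = E[a e^eta / (a e^eta + c)] with eta ~ N(0, ~3.2)
    # solved numerically for c at a = 0.05 (the linear predictor's spread
    # inflates the naive a/(a+c) rate)
    baseline_rate <- 0.05; censoring_rate <- 0.265
  } else {
    ac <- anticorrelated_structure()
    str <- ac$structure
    flip <- ac$flip_genes
    rho <- 0.9; n <- 300L
    signal_clusters <- vapply(str$group_clusters[1:3], `[[`, character(1), 1L)
    true_beta <- stats::setNames(c(1, -1, 1), signal_clusters)
    true_gamma <- c(grade_high = 0.4, age_std = 0.2)
    baseline_rate <- 0.08; censoring_rate <- 0.12
  }
  sim <- simulate_expression(str, n, rho, flip_genes = flip, seed = s(2))
  clin <- simulate_clinical(colnames(sim$expression$values), seed = s(3))
  gamma_used <- true_gamma[colnames(clin$values)]
  surv <- simulate_survival(sim$factors, true_beta, clin$values, gamma_used,
                            baseline_rate, censoring_rate, seed = s(4))
  dataset <- assemble_dataset(sim$expression, surv, clin, str$groups)
  truth <- structure(
    list(preset = preset, seed = seed, structure = str, flip_genes = flip,
         true_beta = true_beta, true_gamma = gamma_used,
         within_cluster_rho = rho, n_samples = n,
         baseline_rate = baseline_rate, censoring_rate = censoring_rate),
    class = "SimulationTruth"
  )
  list(dataset = dataset, truth = truth, factors = sim$factors)
}

#' Serialize simulation ground truth to JSON
#'
#' @param truth a `SimulationTruth`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "SimulationTruth"))
  obj <- list(
    preset = truth$preset, seed = truth$seed,
    flip_genes = truth$flip_genes,
    true_beta = as.list(truth$true_beta),
    true_gamma = as.list(truth$true_gamma),
    within_cluster_rho = truth$within_cluster_rho,
    n_samples = truth$n_samples,
    baseline_rate = truth$baseline_rate,
    censoring_rate = truth$censoring_rate,
    clusters = truth$structure$clusters,
    groups = unclass(truth$structure$groups)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read simulation ground truth back from JSON
#'
#' @param path JSON path written by [write_truth()]
#' @return a list mirroring the serialized fields
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$true_beta <- unlist(obj$true_beta) %||% numeric(0)
  obj$true_gamma <- unlist(obj$true_gamma) %||% numeric(0)
  obj
}
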