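# Experimental protocol: repeated random 2:1 train/test splits, per-split
# preclustering / design construction / CVPL tuning / fitting / evaluation for
# every method x covariate-mode combination, and aggregation into per-split
# metric tables, covariate selection frequencies and averaged prediction-error
# curves.

#' Random 2:1 train/test split
#'
#' Uniformly random partition with |train| = floor(2n/3); deterministic given
#' the seed.
#'
#' @param n number of samples (>= 3)
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
split_data <- function(n, seed = 1L) {
  if (n < 3L) stop("need at least 3 samples to split 2:1", call. = FALSE)
  set.seed(seed)
  n_train <- floor(2 * n / 3)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

harness_defaults <- function() {
  list(M = 10L, t_star = 10, k_max = 20L, nlambda = 50L, grid = NULL,
       master_seed = 1L, precluster_on_full = FALSE, preclustered = NULL,
       keep_fit = FALSE)
}

#' Fit and evaluate one train/test split
#'
#' Runs the full per-split pipeline: preclustering on the training samples
#' (for mode `"preclustered"`), design construction and covariate
#' standardization on training data, 10-fold CVPL tuning of lambda, a final
#' fit on the whole training set, projection of the test samples with frozen
#' training constants, and the three test-set evaluation criteria (logrank on
#' median-split risk groups, prognostic-index LRT, integrated Brier score up
#' to t* years).
#'
#' @param dataset a `Dataset`
#' @param split a [split_data()] result (indices into `dataset$sample_ids`)
#' @param method `"l1"` or `"l2"`
#' @param mode `"genes"`, `"groups"`, `"preclustered"` or `"clinical_only"`
#' @param with_clinical include the clinical covariates as unpenalized
#'   mandatory variables
#' @param config optional list: `M` (CV folds, 10), `t_star` (10 years),
#'   `k_max` (20), `nlambda` (50), `grid` (explicit lambda grid),
#'   `master_seed`, `precluster_on_full` (reuse a precomputed full-data
#'   preclustering in `preclustered`), `keep_fit` (attach fit artifacts)
#' @param seed integer seed for the CV fold assignment
#' @return an object of class `SplitResult`: list with `p_LR`, `p_PI`, `IBS`,
#'   `lambda`, `n_selected`, `method`, `mode`, `with_clinical`, `error`
#'   (NA on success) and, when `keep_fit`, the training artifacts
#' @export
run_single_split <- function(dataset, split, method = c("l1", "l2"),
                             mode = c("genes", "groups", "preclustered", "clinical_only"),
                             with_clinical = TRUE, config = list(), seed = 1L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  cfg <- merge_config(harness_defaults(), config)
  stopifnot(inherits(dataset, "Dataset"))
  train_ids <- dataset$sample_ids[split$train]
  test_ids <- dataset$sample_ids[split$test]
  train_ds <- subset_dataset(dataset, train_ids)

  surv_train <- train_ds$survival
  surv_test <- subset_dataset(dataset, test_ids)$survival
  Z_train <- if (with_clinical) train_ds$clinical$values else NULL
  Z_test <- if (with_clinical) {
    dataset$clinical$values[match(test_ids, dataset$clinical$sample_ids), , drop = FALSE]
  } else NULL

  res <- list(method = method, mode = mode, with_clinical = with_clinical,
              p_LR = NA_real_, p_PI = NA_real_, IBS = NA_real_,
              lambda = NA_real_, n_selected = NA_integer_, error = NA_character_)
  class(res) <- "SplitResult"

  out <- tryCatch({
    if (mode == "clinical_only") {
      if (is.null(Z_train) || ncol(Z_train) == 0L) {
        stop("clinical_only mode needs clinical covariates", call. = FALSE)
      }
      input_train <- risk_model_input(NULL, Z_train, surv_train)
      fit <- fit_penalized_cox(input_train, "none", 0)
      design <- NULL
      X_test <- NULL
      lambda <- NA_real_
      n_selected <- 0L
      preclustered <- NULL
    } else {
      preclustered <- NULL
      if (mode == "preclustered") {
        preclustered <- if (cfg$precluster_on_full && !is.null(cfg$preclustered)) {
          cfg$preclustered
        } else {
          precluster_all_groups(train_ds, k_max = cfg$k_max)
        }
      }
      design <- build_design(train_ds, mode, preclustered = preclustered)
      input_train <- risk_model_input(design$X, Z_train, surv_train)
      tl <- tune_lambda(input_train, method, M = cfg$M, grid = cfg$grid,
                        nlambda = cfg$nlambda, seed = seed)
      lambda <- tl$lambda
      fit <- fit_penalized_cox(input_train, method, lambda)
      X_test <- project_design(design, dataset, test_ids)
      n_selected <- if (method == "l1") sum(fit$beta != 0) else length(fit$beta)
    }

    pi_test <- prognostic_index(fit, X_test, Z_test)
    labels <- suppressWarnings(assign_risk_groups(pi_test))
    p_lr <- if (any(labels) && !all(labels)) {
      logrank_test(labels, surv_test)$p_value
    } else NA_real_
    p_pi <- tryCatch(pi_lrt(pi_test, surv_test), error = function(e) NA_real_)

    baseline <- breslow_baseline(fit, input_train)
    G_test <- km_censoring(surv_test)
    t_usable <- if (length(G_test$times) > 0 && min(G_test$surv) <= 0) {
      max(surv_test$time[surv_test$time < G_test$times[which(G_test$surv <= 0)[1L]]], 0)
    } else {
      max(surv_test$time)
    }
    t_star <- cfg$t_star
    if (t_usable < t_star) {
      warning(sprintf("censoring support ends at %.3g; truncating t* from %.3g",
                      t_usable, t_star), call. = FALSE)
      t_star <- t_usable
    }
    curve <- brier_curve(fit, baseline, X_test, Z_test, surv_test, t_star = t_star)
    ibs <- integrated_brier_score(curve, t_star = t_star)

    res$p_LR <- p_lr
    res$p_PI <- p_pi
    res$IBS <- ibs
    res$lambda <- lambda
    res$n_selected <- n_selected
    res$t_star <- t_star
    if (cfg$keep_fit) {
      res$fit <- fit
      res$design <- design
      res$preclustered <- preclustered
      res$pi_test <- pi_test
      res$curve <- curve
    } else {
      # always keep the coefficient vector: selection frequencies need it
      res$beta <- fit$beta
      res$design_meta <- if (!is.null(design)) design$meta else NULL
      res$curve <- curve
    }
    res
  }, error = function(e) {
    res$error <- conditionMessage(e)
    res
  })
  out
}

# selection-frequency key: covariates must be identifiable across splits even
# though preclustering is retrained per split -- use (group, medoid) for
# clusters, the id itself for genes/groups
covariate_key <- function(meta) {
  if (!is.na(meta$medoid %||% NA) && !is.na(meta$group_id %||% NA)) {
    paste(meta$group_id, meta$medoid, sep = "|")
  } else {
    meta$covariate_id
  }
}

#' Run the full repeated-split evaluation protocol
#'
#' Applies [run_single_split()] to `n_splits` random 2:1 splits (shared across
#' all method x mode combinations; split m uses seed `master_seed + m`),
#' collects the per-split metrics, counts how often each covariate receives a
#' nonzero L1 coefficient (keyed by (group, medoid) for preclustered
#' covariates so the count survives retrained clusterings), records the
#' majority effect sign, and averages the prediction-error curves.
#'
#' @param dataset a `Dataset`
#' @param n_splits number of random splits (the reference protocol uses 100)
#' @param methods subset of `c("l1", "l2")`
#' @param modes subset of `c("genes", "groups", "preclustered",
#'   "clinical_only")`
#' @param with_clinical include clinical covariates in the genomic models
#' @param config see [run_single_split()]; `master_seed` seeds everything
#' @return an object of class `EvaluationSummary`: `results` (data.frame of
#'   split metrics), `selection` (L1 selection-frequency table), `curves`
#'   (averaged `PredictionErrorCurve` per method x mode), `n_failed`, `config`
#' @export
run_evaluation <- function(dataset, n_splits = 100L,
                           methods = c("l1", "l2"),
                           modes = c("genes", "groups", "preclustered"),
                           with_clinical = TRUE, config = list()) {
  stopifnot(inherits(dataset, "Dataset"), n_splits >= 1L)
  if (length(modes) == 0L) stop("empty mode list", call. = FALSE)
  cfg <- merge_config(harness_defaults(), config)
  n <- length(dataset$sample_ids)
  splits <- lapply(seq_len(n_splits), function(m) split_data(n, seed = cfg$master_seed + m))

  rows <- list()
  curves <- list()
  sel <- new.env(parent = emptyenv())
  n_failed <- 0L
  for (m in seq_len(n_splits)) {
    for (method in methods) {
      for (mode in modes) {
        sr <- run_single_split(dataset, splits[[m]], method, mode,
                               with_clinical = with_clinical, config = config,
                               seed = derive_seed(cfg$master_seed, m))
        if (!is.na(sr$error)) {
          n_failed <- n_failed + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          split_id = m, method = method, mode = mode,
          with_clinical = with_clinical, p_LR = sr$p_LR, p_PI = sr$p_PI,
          IBS = sr$IBS, lambda = sr$lambda, n_selected = sr$n_selected,
          stringsAsFactors = FALSE)
        key <- paste(method, mode, sep = ".")
        curves[[key]] <- c(curves[[key]], list(sr$curve))
        if (method == "l1" && !is.null(sr$design_meta)) {
          nz <- which(sr$beta != 0)
          for (j in nz) {
            meta <- sr$design_meta[[j]]
            k <- covariate_key(meta)
            rec <- get0(k, envir = sel, ifnotfound = NULL)
            if (is.null(rec)) {
              rec <- list(key = k, mode = mode, group_id = meta$group_id,
                          medoid = meta$medoid, count = 0L,
                          signs = integer(0), sizes = integer(0))
            }
            rec$count <- rec$count + 1L
            rec$signs <- c(rec$signs, sign(sr$beta[j]))
            rec$sizes <- c(rec$sizes, length(meta$genes))
            assign(k, rec, envir = sel)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) stop("all splits failed", call. = FALSE)
  results <- do.call(rbind, rows)

  sel_rows <- lapply(ls(sel, sorted = TRUE), function(k) {
    rec <- get(k, envir = sel)
    data.frame(covariate = rec$key, mode = rec$mode,
               group_id = rec$group_id %||% NA_character_,
               medoid = rec$medoid %||% NA_character_,
               count = rec$count,
               effect = if (mean(rec$signs > 0) >= 0.5) 1L else -1L,
               cluster_size = stats::median(rec$sizes),
               stringsAsFactors = FALSE)
  })
  selection <- if (length(sel_rows) > 0L) {
    out <- do.call(rbind, sel_rows)
    out[order(-out$count, out$covariate), , drop = FALSE]
  } else {
    data.frame(covariate = character(0), mode = character(0),
               group_id = character(0), medoid = character(0),
               count = integer(0), effect = integer(0), cluster_size = numeric(0))
  }
  rownames(selection) <- NULL

  avg_curves <- lapply(curves, prediction_error_curve)
  structure(
    list(results = results, selection = selection, curves = avg_curves,
         n_failed = n_failed, n_splits = n_splits, methods = methods,
         modes = modes, with_clinical = with_clinical,
         config = cfg[c("M", "t_star", "k_max", "nlambda", "master_seed")]),
    class = "EvaluationSummary"
  )
}

#' @export
print.EvaluationSummary <- function(x, ...) {
  cat(sprintf("EvaluationSummary: %d splits x {%s} x {%s}, %d failed\n",
              x$n_splits, paste(x$methods, collapse = ","),
              paste(x$modes, collapse = ","), x$n_failed))
  agg <- stats::aggregate(cbind(p_LR, p_PI, IBS) ~ method + mode, data = x$results,
                          FUN = stats::median)
  print(agg, digits = 3)
  invisible(x)
}

#' Stable content hash of an evaluation summary
#'
#' MD5 of the serialized summary object; identical master seeds must produce
#' identical hashes.
#'
#' @param summary an `EvaluationSummary` (or any R object)
#' @return hex digest string
#' @export
summary_hash <- function(summary) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(summary, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Write evaluation reports
#'
#' Writes the per-split metrics TSV, the L1 selection-frequency TSV, a
#' long-format metrics table for boxplots, the averaged prediction-error
#' curves as TSV, and (optionally) PDF boxplots of -log10 p-values and IBS
#' plus the averaged prediction-error curves with a clinical reference line.
#'
#' @param summary an `EvaluationSummary`
#' @param outdir output directory (created if missing)
#' @param plots also render PDF figures
#' @return invisibly, the vector of written file paths
#' @export
report <- function(summary, outdir, plots = TRUE) {
  stopifnot(inherits(summary, "EvaluationSummary"))
  if (nrow(summary$results) == 0L) stop("empty summary", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir, call. = FALSE)
  paths <- character(0)

  f <- file.path(outdir, "metrics.tsv")
  utils::write.table(summary$results, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)

  f <- file.path(outdir, "selection.tsv")
  utils::write.table(summary$selection, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)

  long <- stats::reshape(summary$results,
                         varying = c("p_LR", "p_PI", "IBS"),
                         v.names = "value", timevar = "metric",
                         times = c("p_LR", "p_PI", "IBS"),
                         direction = "long")
  rownames(long) <- NULL
  long$id <- NULL
  f <- file.path(outdir, "metrics_long.tsv")
  utils::write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)

  pec <- do.call(rbind, lapply(names(summary$curves), function(k) {
    cv <- summary$curves[[k]]
    data.frame(model = k, time = cv$time, bs = cv$bs)
  }))
  f <- file.path(outdir, "prediction_error_curves.tsv")
  utils::write.table(pec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)

  if (plots) {
    res <- summary$results
    res$model <- paste(res$method, res$mode, sep = ".")
    f <- file.path(outdir, "boxplots.pdf")
    grDevices::pdf(f, width = 9, height = 6)
    op <- graphics::par(mfrow = c(1, 3), mar = c(8, 4, 2, 1))
    graphics::boxplot(-log10(p_LR) ~ model, data = res, las = 2,
                      main = "logrank", ylab = "-log10 p", xlab = "")
    graphics::boxplot(-log10(p_PI) ~ model, data = res, las = 2,
                      main = "prognostic index", ylab = "-log10 p", xlab = "")
    graphics::boxplot(IBS ~ model, data = res, las = 2,
                      main = "integrated Brier score", ylab = "IBS", xlab = "")
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, f)

    f <- file.path(outdir, "prediction_error_curves.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    cols <- grDevices::hcl.colors(max(2L, length(summary$curves)), "Dark 3")
    ylim <- c(0, max(unlist(lapply(summary$curves, `[[`, "bs"))))
    graphics::plot(NULL, xlim = c(0, max(unlist(lapply(summary$curves, `[[`, "time")))),
                   ylim = ylim, xlab = "years", ylab = "Brier score",
                   main = "averaged prediction error curves")
    for (i in seq_along(summary$curves)) {
      cv <- summary$curves[[i]]
      graphics::lines(cv$time, cv$bs, type = "s", col = cols[i], lwd = 2,
                      lty = if (grepl("clinical_only", names(summary$curves)[i])) 2 else 1)
    }
    graphics::legend("bottomright", legend = names(summary$curves),
                     col = cols[seq_along(summary$curves)], lwd = 2, cex = 0.8)
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  invisible(paths)
}
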