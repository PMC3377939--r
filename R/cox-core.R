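# Cox partial likelihood core: Breslow-ties log partial likelihood, exact
# Newton-Raphson for unpenalized and ridge (L2) fits, IRLS + coordinate
# descent for lasso (L1) fits with unpenalized mandatory clinical covariates,
# and cross-validated partial likelihood (CVPL) tuning of the penalty.
#
# The penalty parameter lambda is on the scale of the summed log partial
# likelihood: the L1 objective is l(beta, gamma) - lambda * sum(|beta_j|),
# the L2 objective l(beta, gamma) - lambda * sum(beta_j^2).  Only the genomic
# block beta is penalized.

#' Bundle design blocks and survival response for model fitting
#'
#' @param X genomic covariate matrix (samples x p), or `NULL` for a
#'   clinical-only model
#' @param Z clinical covariate matrix (samples x q), or `NULL`
#' @param survival a [survival_response()] aligned to the rows of `X`/`Z`
#' @return an object of class `RiskModelInput`
#' @export
risk_model_input <- function(X = NULL, Z = NULL, survival) {
  stopifnot(inherits(survival, "SurvivalResponse"))
  n <- length(survival$time)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("X row count must match survival response", call. = FALSE)
    if (any(!is.finite(X))) stop("X contains missing values", call. = FALSE)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  } else {
    X <- matrix(0, n, 0L)
  }
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stop("Z row count must match survival response", call. = FALSE)
    if (any(!is.finite(Z))) stop("Z contains missing values", call. = FALSE)
    if (ncol(Z) > 0L && is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  } else {
    Z <- matrix(0, n, 0L)
  }
  structure(list(X = X, Z = Z, time = survival$time, event = survival$event,
                 sample_ids = survival$sample_ids),
            class = "RiskModelInput")
}

# Breslow-ties quantities at a given linear predictor eta:
# log partial likelihood, per-subject gradient g_i = dl/deta_i, diagonal
# curvature w_i = -d2l/deta_i^2 (diagonal approximation), and the event-time
# grid with risk-set sums (reused by the Breslow baseline estimator).
cox_lp_stats <- function(eta, time, event) {
  if (any(!is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  ord <- order(time)
  ts <- time[ord]
  ev <- event[ord]
  es <- exp(eta[ord])
  rs <- rev(cumsum(rev(es)))              # sum of exp(eta) over {j: t_j >= t}
  first <- !duplicated(ts)
  ut <- ts[first]
  S0u <- rs[first]
  d_u <- as.vector(rowsum(ev, match(ts, ut)))
  is_ev <- d_u > 0
  te <- ut[is_ev]
  de <- d_u[is_ev]
  S0e <- S0u[is_ev]
  e <- exp(eta)
  if (length(te) == 0L) {
    return(list(loglik = 0, g = numeric(length(eta)), w = numeric(length(eta)),
                event_times = numeric(0), d = numeric(0), S0 = numeric(0)))
  }
  A <- cumsum(de / S0e)
  B <- cumsum(de / S0e^2)
  pos <- findInterval(time, te)
  a <- c(0, A)[pos + 1L]
  b <- c(0, B)[pos + 1L]
  list(loglik = sum(eta[event == 1]) - sum(de * log(S0e)),
       g = event - e * a,
       w = pmax(e * a - e^2 * b, 0),
       event_times = te, d = de, S0 = S0e)
}

# exact Hessian of the Breslow log partial likelihood w.r.t. coefficients
cox_hessian <- function(XX, eta, time, event) {
  P <- ncol(XX)
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  ds <- event[ord]
  es <- exp(eta[ord])
  Xs <- XX[ord, , drop = FALSE]
  H <- matrix(0, P, P)
  r0 <- 0
  r1 <- numeric(P)
  r2 <- matrix(0, P, P)
  i <- 1L
  n <- length(ts)
  while (i <= n) {
    j <- i
    while (j <= n && ts[j] == ts[i]) j <- j + 1L
    idx <- i:(j - 1L)
    Xi <- Xs[idx, , drop = FALSE]
    ex <- es[idx] * Xi
    r0 <- r0 + sum(es[idx])
    r1 <- r1 + colSums(ex)
    r2 <- r2 + crossprod(Xi, ex)
    dk <- sum(ds[idx])
    if (dk > 0) {
      m1 <- r1 / r0
      H <- H - dk * (r2 / r0 - tcrossprod(m1))
    }
    i <- j
  }
  H
}

# Newton-Raphson with step halving for the (optionally L2-penalized) log
# partial likelihood; pen marks the penalized coordinates.
cox_newton <- function(XX, time, event, pen, lambda2 = 0, init = NULL,
                       maxit = 200L, grad_tol = 1e-8) {
  P <- ncol(XX)
  theta <- init %||% numeric(P)
  penv <- as.numeric(pen)
  obj_fun <- function(th, st) st$loglik - lambda2 * sum(penv * th^2)
  eta <- drop(XX %*% theta)
  st <- cox_lp_stats(eta, time, event)
  obj <- obj_fun(theta, st)
  trace <- obj
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    grad <- drop(crossprod(XX, st$g)) - 2 * lambda2 * penv * theta
    if (max(abs(grad)) < grad_tol * (1 + abs(st$loglik))) {
      converged <- TRUE
      break
    }
    H <- cox_hessian(XX, eta, time, event)
    A <- -H + diag(2 * lambda2 * penv + 1e-10, P)
    delta <- tryCatch(solve(A, grad), error = function(e) NULL)
    if (is.null(delta)) delta <- solve(A + diag(1e-6, P), grad)
    s <- 1
    repeat {
      cand <- theta + s * delta
      eta_c <- drop(XX %*% cand)
      if (max(abs(eta_c)) > 250) {
        if (lambda2 == 0 && s == 1) {
          stop("partial likelihood maximization diverged (unbounded linear predictor); ",
               "the unpenalized model may be separable", call. = FALSE)
        }
        s <- s / 2
        next
      }
      st_c <- cox_lp_stats(eta_c, time, event)
      obj_c <- obj_fun(cand, st_c)
      if (obj_c >= obj - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    if (obj_c < obj - 1e-8) break            # no ascent possible: give up
    theta <- cand
    eta <- eta_c
    st <- st_c
    obj <- obj_c
    trace <- c(trace, obj)
  }
  list(theta = theta, converged = converged, n_iter = it,
       objective = obj, obj_trace = trace, loglik = st$loglik)
}

# IRLS + coordinate descent for the L1-penalized log partial likelihood;
# soft-thresholding gives exact zeros for penalized coordinates.
cox_l1 <- function(XX, time, event, pen, lambda, init = NULL,
                   tol = 1e-6, maxit = 200L) {
  P <- ncol(XX)
  theta <- init %||% numeric(P)
  penl <- as.logical(pen)
  eta <- drop(XX %*% theta)
  st <- cox_lp_stats(eta, time, event)
  obj <- st$loglik - lambda * sum(abs(theta[penl]))
  trace <- obj
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    w <- pmax(st$w, 1e-9)
    z <- eta + st$g / w
    theta_new <- .cd_wls(XX, w, z, lambda, penl, theta, 1e-7, 300L)
    s <- 1
    repeat {
      cand <- theta + s * (theta_new - theta)
      eta_c <- drop(XX %*% cand)
      ok <- max(abs(eta_c)) < 250
      if (ok) {
        st_c <- cox_lp_stats(eta_c, time, event)
        obj_c <- st_c$loglik - lambda * sum(abs(cand[penl]))
      } else {
        obj_c <- -Inf
      }
      if (obj_c >= obj - 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    if (!is.finite(obj_c) || obj_c < obj - 1e-8) break
    delta_obj <- obj_c - obj
    theta <- cand
    eta <- eta_c
    st <- st_c
    obj <- obj_c
    trace <- c(trace, obj)
    if (delta_obj < tol * (abs(obj) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, converged = converged, n_iter = it,
       objective = obj, obj_trace = trace, loglik = st$loglik)
}

new_coxfit <- function(res, p, q, xnames, znames, penalty, lambda) {
  structure(
    list(beta = stats::setNames(res$theta[seq_len(p)], xnames),
         gamma = stats::setNames(res$theta[p + seq_len(q)], znames),
         penalty = penalty, lambda = lambda, converged = res$converged,
         n_iter = res$n_iter, objective = res$objective,
         obj_trace = res$obj_trace, loglik = res$loglik),
    class = "CoxFit"
  )
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("CoxFit: penalty %s, lambda %.4g, %d/%d nonzero genomic coefficients, %d clinical\n",
              x$penalty, x$lambda, sum(x$beta != 0), length(x$beta), length(x$gamma)))
  invisible(x)
}

#' Cox log partial likelihood (Breslow ties)
#'
#' Evaluates sum_i delta_i \[eta_i - log sum_\{j in R(t_i)\} exp(eta_j)\] with
#' eta = X beta + Z gamma and risk set R(t_i) = \{j : t_j >= t_i\}; tied event
#' times share the full risk set (Breslow convention).
#'
#' @param beta genomic coefficient vector (length p)
#' @param gamma clinical coefficient vector (length q)
#' @param input a [risk_model_input()]
#' @return the log partial likelihood (0 when there are no events)
#' @export
log_partial_likelihood <- function(beta, gamma, input) {
  stopifnot(inherits(input, "RiskModelInput"))
  if (length(beta) != ncol(input$X) || length(gamma) != ncol(input$Z)) {
    stop("coefficient lengths do not match the design", call. = FALSE)
  }
  eta <- drop(input$X %*% beta) + drop(input$Z %*% gamma)
  if (length(eta) == 0L) eta <- numeric(length(input$time))
  cox_lp_stats(eta, input$time, input$event)$loglik
}

#' Fit a penalized Cox model with unpenalized clinical covariates
#'
#' Maximizes the penalized log partial likelihood with the penalty applied to
#' the genomic block only.  `penalty = "l1"` uses iteratively reweighted least
#' squares with cyclic coordinate descent (exact zeros via soft-thresholding);
#' `"l2"` and `"none"` use exact Newton-Raphson with step halving.  With
#' `lambda = 0` all penalties coincide with the unpenalized fit, which is then
#' computed by Newton-Raphson.
#'
#' @param input a [risk_model_input()]
#' @param penalty `"l1"`, `"l2"` or `"none"`
#' @param lambda nonnegative penalty weight, on the summed log partial
#'   likelihood scale
#' @param control optional list: `tol` (relative objective change, default
#'   1e-6), `maxit` (default 200), `init` (warm-start coefficient vector)
#' @return an object of class `CoxFit` with fields `beta`, `gamma`, `penalty`,
#'   `lambda`, `converged`, `n_iter`, `objective` and the per-iteration
#'   `obj_trace`
#' @export
fit_penalized_cox <- function(input, penalty = c("l1", "l2", "none"), lambda = 0,
                              control = list()) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(input, "RiskModelInput"))
  if (!is_scalar_number(lambda) || lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (penalty == "none" && lambda != 0) stop("penalty 'none' requires lambda = 0", call. = FALSE)
  if (sum(input$event) == 0L) {
    stop("no events: the partial likelihood is identically zero", call. = FALSE)
  }
  ctl <- merge_config(list(tol = 1e-6, maxit = 200L, init = NULL), control)
  p <- ncol(input$X)
  q <- ncol(input$Z)
  if (p + q == 0L) stop("model has no covariates", call. = FALSE)
  XX <- cbind(input$X, input$Z)
  pen <- c(rep(TRUE, p), rep(FALSE, q))

  res <- if (penalty == "l2" && lambda > 0) {
    cox_newton(XX, input$time, input$event, pen, lambda2 = lambda,
               init = ctl$init, maxit = ctl$maxit)
  } else if (penalty == "l1" && lambda > 0) {
    init <- ctl$init
    if (is.null(init) && q > 0L) {
      # warm start: clinical-only fit, genomic block at zero
      gfit <- cox_newton(input$Z, input$time, input$event, rep(FALSE, q),
                         maxit = ctl$maxit)
      init <- c(numeric(p), gfit$theta)
    }
    cox_l1(XX, input$time, input$event, pen, lambda, init = init,
           tol = ctl$tol, maxit = ctl$maxit)
  } else {
    cox_newton(XX, input$time, input$event, pen, lambda2 = 0,
               init = ctl$init, maxit = ctl$maxit)
  }
  if (!res$converged) {
    warning("penalized Cox fit did not converge in ", ctl$maxit, " iterations",
            call. = FALSE)
  }
  new_coxfit(res, p, q, colnames(input$X), colnames(input$Z), penalty, lambda)
}

#' Smallest L1 penalty that zeroes every genomic coefficient
#'
#' Computed from the score at beta = 0 with gamma at its clinical-only
#' maximum: lambda_max = max_j |X_j' g|, where g is the gradient of the log
#' partial likelihood with respect to the linear predictor.
#'
#' @param input a [risk_model_input()] with a nonempty genomic block
#' @return the scalar lambda_max
#' @export
compute_lambda_max <- function(input) {
  stopifnot(inherits(input, "RiskModelInput"))
  if (ncol(input$X) == 0L) stop("no genomic covariates", call. = FALSE)
  q <- ncol(input$Z)
  eta <- if (q > 0L) {
    gfit <- cox_newton(input$Z, input$time, input$event, rep(FALSE, q))
    drop(input$Z %*% gfit$theta)
  } else {
    numeric(length(input$time))
  }
  g <- cox_lp_stats(eta, input$time, input$event)$g
  max(abs(drop(crossprod(input$X, g))))
}

#' Event-stratified cross-validation folds
#'
#' Random fold assignment stratified by event status so that every fold
#' contains at least one event whenever the data has >= M events.
#'
#' @param event 0/1 event indicator vector
#' @param M number of folds (>= 2)
#' @param seed integer seed
#' @return integer vector of fold labels in 1..M
#' @export
make_cv_folds <- function(event, M = 10L, seed = NULL) {
  M <- as.integer(M)
  if (M < 2L) stop("M must be >= 2", call. = FALSE)
  if (sum(event == 1) < M) {
    stop("cannot form ", M, " folds that each contain an event (only ",
         sum(event == 1), " events)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(event))
  idx_e <- which(event == 1)
  idx_c <- which(event == 0)
  fold[sample(idx_e)] <- rep_len(seq_len(M), length(idx_e))
  if (length(idx_c) > 0L) fold[sample(idx_c)] <- rep_len(rev(seq_len(M)), length(idx_c))
  fold
}

subset_input <- function(input, keep) {
  si <- survival_response(input$sample_ids[keep], input$time[keep], input$event[keep])
  risk_model_input(
    X = if (ncol(input$X) > 0L) input$X[keep, , drop = FALSE] else NULL,
    Z = if (ncol(input$Z) > 0L) input$Z[keep, , drop = FALSE] else NULL,
    survival = si
  )
}

#' Cross-validated log partial likelihood (CVPL)
#'
#' For each fold m, parameters are estimated without the fold and the fold's
#' contribution is l(theta_hat) - l_(-m)(theta_hat): the log partial
#' likelihood over all patients minus the one over all patients except fold m,
#' both at the leave-fold-out estimates.  The sum over folds is returned;
#' larger is better.
#'
#' @param input a [risk_model_input()]
#' @param penalty `"l1"` or `"l2"`
#' @param lambda penalty weight
#' @param M number of folds (default 10)
#' @param seed integer seed for fold assignment
#' @param folds optional precomputed fold labels (overrides `M`/`seed`)
#' @param fixed optional `list(beta, gamma)`; when given, refitting is skipped
#'   and the formula is evaluated at these coefficients (testing hook)
#' @return the CVPL value, with the per-fold contributions in attribute
#'   `"per_fold"`
#' @export
cvpl <- function(input, penalty = c("l1", "l2"), lambda, M = 10L, seed = NULL,
                 folds = NULL, fixed = NULL) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(input, "RiskModelInput"))
  folds <- folds %||% make_cv_folds(input$event, M, seed)
  M <- max(folds)
  if (any(vapply(seq_len(M), function(m) sum(input$event[folds != m]) == 0L, logical(1)))) {
    stop("a training fold complement has no events", call. = FALSE)
  }
  per_fold <- vapply(seq_len(M), function(m) {
    sub <- subset_input(input, folds != m)
    if (is.null(fixed)) {
      fit <- fit_penalized_cox(sub, penalty, lambda)
      beta <- fit$beta
      gamma <- fit$gamma
    } else {
      beta <- fixed$beta
      gamma <- fixed$gamma
    }
    log_partial_likelihood(beta, gamma, input) - log_partial_likelihood(beta, gamma, sub)
  }, numeric(1))
  structure(sum(per_fold), per_fold = per_fold)
}

default_lambda_grid <- function(input, penalty, nlambda) {
  n <- length(input$time)
  p <- max(1L, ncol(input$X))
  if (penalty == "l1") {
    lmax <- compute_lambda_max(input)
    if (!is.finite(lmax) || lmax <= 0) lmax <- 1
    lmax <- lmax * (1 + 1e-6)      # strictly above the activation boundary
    exp(seq(log(lmax), log(0.01 * lmax), length.out = nlambda))
  } else {
    # broad log grid scaled by the n/p heuristic; ridge optima move with scale
    10^seq(-2, 6, length.out = nlambda) * (n / p)
  }
}

#' Tune the penalty by cross-validated partial likelihood
#'
#' Evaluates [cvpl()] over a lambda grid with fold memberships shared across
#' all grid points and warm starts along the decreasing-lambda path, and
#' returns the maximizer (ties resolved toward the larger lambda, the more
#' parsimonious model).
#'
#' @param input a [risk_model_input()]
#' @param penalty `"l1"` or `"l2"`
#' @param M number of cross-validation folds (default 10)
#' @param grid lambda grid; default for `"l1"` is 50 log-spaced values from
#'   lambda_max down to 0.01 lambda_max, for `"l2"` 50 log-spaced values over
#'   \[1e-2, 1e6\] times n/p
#' @param nlambda grid size when `grid` is `NULL`
#' @param seed integer seed for the fold assignment
#' @param df_max saturation guard for the L1 path: once a leave-fold-out fit
#'   selects at least this many covariates, smaller lambdas are skipped for
#'   that fold (they sit deep in the overfitting regime and cannot win the
#'   CVPL argmax).  Default: 90\% of the fold's event count, capped at p.
#' @return an object of class `LambdaTuning`: `lambda` (the maximizer),
#'   `grid`, `cvpl` (the curve), `folds`
#' @export
tune_lambda <- function(input, penalty = c("l1", "l2"), M = 10L, grid = NULL,
                        nlambda = 50L, seed = NULL, df_max = NULL) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(input, "RiskModelInput"))
  grid <- grid %||% default_lambda_grid(input, penalty, nlambda)
  if (length(grid) == 0L) stop("empty lambda grid", call. = FALSE)
  grid <- sort(unique(grid), decreasing = TRUE)
  folds <- make_cv_folds(input$event, M, seed)
  M <- max(folds)

  contrib <- matrix(NA_real_, nrow = length(grid), ncol = M)
  for (m in seq_len(M)) {
    sub <- subset_input(input, folds != m)
    dmax <- df_max %||% min(ncol(input$X), max(5L, floor(0.9 * sum(sub$event))))
    warm <- NULL
    for (k in seq_along(grid)) {
      fit <- tryCatch(
        suppressWarnings(fit_penalized_cox(sub, penalty, grid[k],
                                           control = list(init = warm))),
        error = function(e) NULL)
      if (is.null(fit)) next
      warm <- c(fit$beta, fit$gamma)
      contrib[k, m] <-
        log_partial_likelihood(fit$beta, fit$gamma, input) -
        log_partial_likelihood(fit$beta, fit$gamma, sub)
      if (penalty == "l1" && sum(fit$beta != 0) >= dmax) break
    }
  }
  curve <- rowSums(contrib)                  # NA when any fold failed
  if (all(is.na(curve))) stop("no lambda on the grid produced a converged fit", call. = FALSE)
  best <- which(curve == max(curve, na.rm = TRUE))[1L]   # grid is descending: ties -> larger lambda
  structure(
    list(lambda = grid[best], grid = grid, cvpl = curve, folds = folds,
         penalty = penalty),
    class = "LambdaTuning"
  )
}

#' Prognostic index (risk score) per sample
#'
#' The linear predictor beta_hat' x_i + gamma_hat' z_i; higher values mean
#' higher hazard.  Clinical-only and genomic-only models are the special cases
#' with an empty block.
#'
#' @param fit a [fit_penalized_cox()] result
#' @param X genomic covariate matrix (or `NULL`)
#' @param Z clinical covariate matrix (or `NULL`)
#' @return numeric vector of risk scores
#' @export
prognostic_index <- function(fit, X = NULL, Z = NULL) {
  stopifnot(inherits(fit, "CoxFit"))
  n <- if (!is.null(X)) nrow(X) else if (!is.null(Z)) nrow(Z) else 0L
  pi <- numeric(n)
  if (length(fit$beta) > 0L) {
    if (is.null(X) || ncol(X) != length(fit$beta)) {
      stop("X does not match the fitted genomic block", call. = FALSE)
    }
    pi <- pi + drop(X %*% fit$beta)
  }
  if (length(fit$gamma) > 0L) {
    if (is.null(Z) || ncol(Z) != length(fit$gamma)) {
      stop("Z does not match the fitted clinical block", call. = FALSE)
    }
    pi <- pi + drop(Z %*% fit$gamma)
  }
  rn <- rownames(X) %||% rownames(Z)
  if (!is.null(rn)) names(pi) <- rn
  pi
}

#' Serialize a Cox fit to TSV plus a JSON header
#'
#' @param fit a `CoxFit`
#' @param coef_path output TSV (covariate_id, coefficient, penalized)
#' @param header_path output JSON (penalty, lambda, convergence)
#' @return invisibly, a list with both paths
#' @export
write_coxfit <- function(fit, coef_path, header_path) {
  stopifnot(inherits(fit, "CoxFit"))
  df <- data.frame(
    covariate_id = c(names(fit$beta), names(fit$gamma)),
    coefficient = c(fit$beta, fit$gamma),
    penalized = c(rep(TRUE, length(fit$beta)), rep(FALSE, length(fit$gamma)))
  )
  utils::write.table(df, coef_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(penalty = fit$penalty, lambda = fit$lambda, converged = fit$converged,
         n_iter = fit$n_iter, objective = fit$objective),
    header_path, auto_unbox = TRUE, digits = NA)
  invisible(list(coefficients = coef_path, header = header_path))
}
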