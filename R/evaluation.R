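# Test-set model assessment: median-split logrank test, prognostic-index
# likelihood-ratio test, Breslow baseline hazard, survival prediction, and
# the IPCW (integrated) Brier score with prediction-error curves.

#' Assign test samples to high/low risk groups by the median prognostic index
#'
#' A sample is high-risk iff its prognostic index is strictly above the median
#' of all test-set prognostic indices; ties at the median go to the low-risk
#' group ("above the median" read literally).
#'
#' @param pi numeric prognostic index vector (>= 2 samples)
#' @return logical vector, `TRUE` = high-risk
#' @export
assign_risk_groups <- function(pi) {
  if (length(pi) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (all(pi == pi[1L])) {
    warning("all prognostic indices identical; everyone assigned to the low-risk group",
            call. = FALSE)
    return(stats::setNames(rep(FALSE, length(pi)), names(pi)))
  }
  stats::setNames(pi > stats::median(pi), names(pi))
}

#' Two-group logrank test
#'
#' Standard logrank statistic: at each event time, observed minus expected
#' events in the high-risk group, with the hypergeometric variance; the
#' statistic is referred to a chi-square distribution with 1 df.
#'
#' @param labels logical (or two-level) group labels, `TRUE` = high-risk
#' @param survival a [survival_response()] aligned to `labels`
#' @return list with `statistic` (chi-square), `p_value`, and the summed
#'   observed/expected counts
#' @export
logrank_test <- function(labels, survival) {
  stopifnot(inherits(survival, "SurvivalResponse"))
  g <- as.logical(labels)
  if (length(g) != length(survival$time)) stop("labels length mismatch", call. = FALSE)
  if (!any(g) || all(g)) stop("both risk groups must be nonempty", call. = FALSE)
  time <- survival$time
  event <- survival$event
  te <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in te) {
    at <- time >= t
    nj <- sum(at)
    n1j <- sum(at & g)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & g)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1) V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Likelihood-ratio test of the prognostic index
#'
#' Fits the univariate Cox model h_i(t) = h_0(t) exp(alpha * PI_i) on the test
#' set and tests alpha = 0 with the likelihood-ratio statistic
#' 2\[l(alpha_hat) - l(0)\] against chi-square with 1 df.  A small p-value
#' means the prognostic index separates short from long survivors.
#'
#' @param pi numeric prognostic index vector (not all equal)
#' @param survival a [survival_response()] aligned to `pi`
#' @return the p-value
#' @export
pi_lrt <- function(pi, survival) {
  stopifnot(inherits(survival, "SurvivalResponse"))
  if (length(pi) != length(survival$time)) stop("length mismatch", call. = FALSE)
  if (all(pi == pi[1L])) stop("prognostic index is constant", call. = FALSE)
  X <- matrix(pi - mean(pi), ncol = 1L, dimnames = list(NULL, "PI"))
  fit <- cox_newton(X, survival$time, survival$event, pen = FALSE)
  if (!fit$converged) stop("prognostic-index Cox fit did not converge", call. = FALSE)
  l0 <- cox_lp_stats(numeric(length(pi)), survival$time, survival$event)$loglik
  stat <- 2 * (fit$loglik - l0)
  stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' H0_hat(t) = sum over event times t_k <= t of d_k / sum_\{j in R(t_k)\}
#' exp(eta_hat_j), a right-continuous step function starting at 0.
#'
#' @param fit a `CoxFit`
#' @param input the training [risk_model_input()] the fit was estimated on
#' @return an object of class `BaselineHazard`: `event_times` (increasing) and
#'   `cumulative_hazard` (nondecreasing)
#' @export
breslow_baseline <- function(fit, input) {
  stopifnot(inherits(fit, "CoxFit"), inherits(input, "RiskModelInput"))
  eta <- drop(input$X %*% fit$beta) + drop(input$Z %*% fit$gamma)
  st <- cox_lp_stats(eta, input$time, input$event)
  structure(
    list(event_times = st$event_times,
         cumulative_hazard = cumsum(st$d / st$S0)),
    class = "BaselineHazard"
  )
}

# H0(t), right-continuous
baseline_at <- function(baseline, t) {
  step_eval(baseline$event_times, baseline$cumulative_hazard, t, v0 = 0)
}

#' Predicted survival probabilities from a Cox fit
#'
#' S_hat(t | x, z) = exp(-H0_hat(t) * exp(beta_hat' x + gamma_hat' z)), with
#' S_hat(0) = 1.
#'
#' @param fit a `CoxFit`
#' @param baseline a [breslow_baseline()] result
#' @param X genomic covariates of the patients to predict (or `NULL`)
#' @param Z clinical covariates (or `NULL`)
#' @param times nonnegative evaluation times
#' @return a patients x times matrix of survival probabilities
#' @export
predict_survival <- function(fit, baseline, X = NULL, Z = NULL, times) {
  stopifnot(inherits(baseline, "BaselineHazard"))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  eta <- prognostic_index(fit, X, Z)
  H0 <- baseline_at(baseline, times)
  out <- exp(-outer(exp(eta), H0))
  dimnames(out) <- list(names(eta), NULL)
  out
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' The product-limit estimator with the roles of event and censoring swapped:
#' censorings are the "events" of G_hat, observed deaths are its censored
#' observations.  Used for the inverse-probability-of-censoring weights of the
#' Brier score.
#'
#' @param survival a [survival_response()]
#' @return an object of class `CensoringDistribution` with jump times and
#'   post-jump values; evaluate with [censoring_at()]
#' @export
km_censoring <- function(survival) {
  stopifnot(inherits(survival, "SurvivalResponse"))
  time <- survival$time
  cens <- 1L - survival$event
  ut <- sort(unique(time))
  n_at <- vapply(ut, function(u) sum(time >= u), numeric(1))
  d_c <- vapply(ut, function(u) sum(time == u & cens == 1L), numeric(1))
  keep <- d_c > 0
  surv <- cumprod(1 - d_c[keep] / n_at[keep])
  structure(
    list(times = ut[keep], surv = surv),
    class = "CensoringDistribution"
  )
}

#' Evaluate the censoring survival function
#'
#' @param G a [km_censoring()] result
#' @param t evaluation times
#' @param left if `TRUE`, return the left limit G_hat(t-)
#' @return G_hat values in \[0, 1\]
#' @export
censoring_at <- function(G, t, left = FALSE) {
  stopifnot(inherits(G, "CensoringDistribution"))
  step_eval(G$times, G$surv, t, v0 = 1, left = left)
}

#' IPCW Brier score at one time point
#'
#' BS(t) = (1/n) sum_i \[ S_hat(t|i)^2 1(t_i <= t, delta_i = 1) / G_hat(t_i-)
#'                      + (1 - S_hat(t|i))^2 1(t_i > t) / G_hat(t) \].
#' Patients censored before t contribute zero.  The event-term weight uses the
#' left limit G_hat(t_i-) (the standard Graf convention).
#'
#' @param t evaluation time (>= 0)
#' @param survival test-set [survival_response()]
#' @param S_hat predicted survival probabilities at `t`, one per patient
#' @param G censoring distribution from [km_censoring()], estimated on the
#'   same test set
#' @return the Brier score at `t`
#' @export
brier_score <- function(t, survival, S_hat, G) {
  stopifnot(inherits(survival, "SurvivalResponse"), inherits(G, "CensoringDistribution"))
  if (length(S_hat) != length(survival$time)) stop("S_hat length mismatch", call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  time <- survival$time
  event <- survival$event
  n <- length(time)
  term <- numeric(n)
  ev <- time <= t & event == 1L
  if (any(ev)) {
    w <- censoring_at(G, time[ev], left = TRUE)
    if (any(w <= 0)) {
      stop("censoring distribution is zero at a required event time; use a smaller t*",
           call. = FALSE)
    }
    term[ev] <- S_hat[ev]^2 / w
  }
  alive <- time > t
  if (any(alive)) {
    gt <- censoring_at(G, t)
    if (gt <= 0) {
      stop("censoring distribution is zero at t; use a smaller t*", call. = FALSE)
    }
    term[alive] <- (1 - S_hat[alive])^2 / gt
  }
  sum(term) / n
}

#' Construct a prediction-error curve on the test set
#'
#' Evaluates the IPCW Brier score on the grid of unique test-set event times
#' in \[0, t*\] plus the endpoints 0 and t*.
#'
#' @param fit a `CoxFit`
#' @param baseline training [breslow_baseline()]
#' @param X,Z test-set covariates
#' @param survival test-set [survival_response()]
#' @param t_star upper end of the evaluation window (years)
#' @return an object of class `PredictionErrorCurve`: `time` grid and `bs`
#'   values
#' @export
brier_curve <- function(fit, baseline, X = NULL, Z = NULL, survival, t_star = 10) {
  G <- km_censoring(survival)
  grid <- sort(unique(c(0, survival$time[survival$event == 1L &
                                           survival$time <= t_star], t_star)))
  S <- predict_survival(fit, baseline, X, Z, times = grid)
  bs <- vapply(seq_along(grid), function(k) {
    brier_score(grid[k], survival, S[, k], G)
  }, numeric(1))
  structure(list(time = grid, bs = bs), class = "PredictionErrorCurve")
}

#' Integrated Brier score
#'
#' IBS = (1/t*) integral of BS(t) over \[0, t*\], computed by the trapezoid
#' rule on the union of the curve's grid and \{0, t*\}.  A missing value at 0
#' is taken as 0 (BS(0) = 0 whenever S_hat(0) = 1); a missing value at t* is
#' carried forward from the last grid point (right-continuous step
#' extension).
#'
#' @param curve a `PredictionErrorCurve` (list with `time` and `bs`)
#' @param t_star upper integration limit, default 10 years
#' @return the integrated Brier score
#' @export
integrated_brier_score <- function(curve, t_star = 10) {
  tt <- curve$time
  bs <- curve$bs
  if (length(tt) == 0L) stop("empty prediction-error curve", call. = FALSE)
  if (any(diff(order(tt)) < 0)) {
    o <- order(tt)
    tt <- tt[o]
    bs <- bs[o]
  }
  if (max(tt) < t_star) {
    tt <- c(tt, t_star)
    bs <- c(bs, bs[length(bs)])
  }
  if (min(tt) > 0) {
    tt <- c(0, tt)
    bs <- c(0, bs)
  }
  keep <- tt <= t_star
  tt <- tt[keep]
  bs <- bs[keep]
  if (tt[length(tt)] < t_star) {          # t_star was dropped by rounding guard
    tt <- c(tt, t_star)
    bs <- c(bs, bs[length(bs)])
  }
  sum(diff(tt) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / t_star
}

#' Average prediction-error curves across splits
#'
#' Curves are resampled to the union grid by right-continuous step
#' interpolation and averaged pointwise.
#'
#' @param curves nonempty list of `PredictionErrorCurve` objects
#' @return a `PredictionErrorCurve` on the union grid
#' @export
prediction_error_curve <- function(curves) {
  if (length(curves) == 0L) stop("no curves to average", call. = FALSE)
  grid <- sort(unique(unlist(lapply(curves, `[[`, "time"))))
  vals <- vapply(curves, function(cv) {
    step_eval(cv$time, cv$bs, grid, v0 = cv$bs[1L])
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  structure(list(time = grid, bs = rowMeans(vals)), class = "PredictionErrorCurve")
}
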