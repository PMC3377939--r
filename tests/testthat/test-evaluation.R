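# evaluation: risk groups, logrank, PI LRT, Breslow, censoring KM, Brier

test_that("median rule assigns risk groups with ties to low risk", {
  g <- assign_risk_groups(c(1, 2, 3, 4))
  expect_equal(unname(g), c(FALSE, FALSE, TRUE, TRUE))
  g2 <- assign_risk_groups(c(1, 2, 2, 3))        # median 2, ties low
  expect_equal(unname(g2), c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(g3 <- assign_risk_groups(c(1, 1, 1)), "identical")
  expect_false(any(g3))
  # odd n: strictly-above-median count is (n-1)/2
  set.seed(71)
  pis <- rnorm(101)
  expect_identical(sum(assign_risk_groups(pis)), 50L)
  expect_error(assign_risk_groups(1), "2 samples")
})

test_that("logrank test matches a hand-computed table and survdiff", {
  # hand-worked 10-patient example
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1)
  grp <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  sv <- survival_response(paste0("s", 1:10), time, event)
  # oracle: explicit observed/expected/variance sums
  O <- E <- V <- 0
  for (t in time[event == 1]) {
    at <- time >= t
    nj <- sum(at); n1j <- sum(at & grp)
    dj <- sum(time == t & event == 1)
    O <- O + sum(time == t & event == 1 & grp)
    E <- E + dj * n1j / nj
    if (nj > 1) V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  lr <- logrank_test(grp, sv)
  expect_equal(lr$statistic, (O - E)^2 / V)
  expect_equal(lr$p_value, pchisq((O - E)^2 / V, 1, lower.tail = FALSE))
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)

  # duplicated groups -> statistic 0, p 1
  sv2 <- survival_response(paste0("s", 1:20), rep(time, 2), rep(event, 2))
  lr2 <- logrank_test(rep(c(TRUE, FALSE), each = 10), sv2)
  expect_equal(lr2$statistic, 0)
  expect_equal(lr2$p_value, 1)
  # label swap invariance
  lr3 <- logrank_test(!grp, sv)
  expect_equal(lr3$statistic, lr$statistic)
  expect_error(logrank_test(rep(TRUE, 10), sv), "nonempty")
})

test_that("PI likelihood-ratio test detects signal and rejects constants", {
  set.seed(72)
  n <- 150
  pi_true <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(pi_true))
  sv <- survival_response(paste0("s", 1:n), tt, rep(1L, n))
  expect_lt(pi_lrt(pi_true, sv), 1e-4)
  expect_error(pi_lrt(rep(1, n), sv), "constant")
  skip_if_not_installed("survival")
  p_or <- summary(survival::coxph(survival::Surv(tt, rep(1, n)) ~ pi_true,
                                  ties = "breslow"))$logtest["pvalue"]
  expect_equal(pi_lrt(pi_true, sv), unname(p_or), tolerance = 1e-6)
})

test_that("Breslow baseline reduces to Nelson-Aalen at zero coefficients", {
  # single event at t=1 among 4 at risk -> H0(1) = 1/4
  sv <- survival_response(paste0("s", 1:4), c(1, 2, 3, 4), c(1, 0, 0, 0))
  inp <- risk_model_input(matrix(0, 4, 1), NULL, sv)
  fit <- structure(list(beta = c(x1 = 0), gamma = numeric(0), penalty = "none",
                        lambda = 0, converged = TRUE), class = "CoxFit")
  bl <- breslow_baseline(fit, inp)
  expect_equal(bl$event_times, 1)
  expect_equal(bl$cumulative_hazard, 0.25)

  # general zero-coefficient case = Nelson-Aalen, with ties
  time <- c(1, 1, 2, 3, 3, 4, 6, 7)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0)
  sv2 <- survival_response(paste0("s", 1:8), time, event)
  inp2 <- risk_model_input(matrix(0, 8, 1), NULL, sv2)
  fit$beta <- c(x1 = 0)
  bl2 <- breslow_baseline(fit, inp2)
  na_oracle <- cumsum(c(2 / 8, 2 / 5, 1 / 2))
  expect_equal(bl2$cumulative_hazard, na_oracle)

  # random nonzero fit: explicit risk-set summation oracle
  d <- make_surv_data(20, p = 2, q = 1, beta = c(0.5, -0.3), gamma = 0.2, seed = 73)
  f <- fit_penalized_cox(d$input, "none", 0)
  bl3 <- breslow_baseline(f, d$input)
  eta <- drop(d$X %*% f$beta + d$Z %*% f$gamma)
  te <- sort(unique(d$survival$time[d$survival$event == 1]))
  oracle <- cumsum(vapply(te, function(u) {
    sum(d$survival$time == u & d$survival$event == 1) /
      sum(exp(eta[d$survival$time >= u]))
  }, numeric(1)))
  expect_equal(bl3$cumulative_hazard, oracle)
})

test_that("predicted survival is 1 at t=0, monotone in t and eta", {
  d <- make_surv_data(30, p = 2, q = 1, beta = c(0.8, -0.4), gamma = 0.2, seed = 74)
  fit <- fit_penalized_cox(d$input, "none", 0)
  bl <- breslow_baseline(fit, d$input)
  tt <- c(0, sort(runif(8, 0, max(d$survival$time))))
  S <- predict_survival(fit, bl, d$X, d$Z, tt)
  expect_equal(unname(S[, 1]), rep(1, 30))
  expect_true(all(apply(S, 1, function(s) all(diff(s) <= 1e-12))))
  # ordering in eta at fixed t
  eta <- prognostic_index(fit, d$X, d$Z)
  ord <- order(eta)
  expect_true(all(diff(S[ord, length(tt)]) <= 1e-12))
  # baseline patient: S = exp(-H0)
  S0 <- predict_survival(fit, bl, matrix(0, 1, 2), matrix(0, 1, 1), tt)
  expect_equal(drop(S0), exp(-preclustsurv:::baseline_at(bl, tt)))
})

test_that("censoring KM matches the product-limit oracle and role swap", {
  # no censoring -> G = 1 everywhere
  sv <- survival_response(paste0("s", 1:5), 1:5, rep(1L, 5))
  G <- km_censoring(sv)
  expect_equal(censoring_at(G, c(0, 2.5, 5)), c(1, 1, 1))

  # all censored at distinct times -> ordinary KM of those times
  sv2 <- survival_response(paste0("s", 1:4), c(1, 2, 3, 4), rep(0L, 4))
  G2 <- km_censoring(sv2)
  expect_equal(censoring_at(G2, c(1, 2, 3)), c(3 / 4, 1 / 2, 1 / 4))

  # mixed 6-patient set against the hand product-limit oracle
  time <- c(0.5, 1, 1.5, 2, 3, 4)
  event <- c(1, 0, 1, 0, 0, 1)
  sv3 <- survival_response(paste0("s", 1:6), time, event)
  G3 <- km_censoring(sv3)
  for (t in c(0.7, 1, 1.9, 2, 3.5, 4)) {
    expect_equal(censoring_at(G3, t), oracle_km(time, 1 - event, t))
  }
  # left limits sit one step behind
  expect_equal(censoring_at(G3, 1, left = TRUE), 1)
  expect_equal(censoring_at(G3, 2, left = TRUE), censoring_at(G3, 1))
  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  expect_equal(censoring_at(G3, sf$time), sf$surv)
})

test_that("Brier score closed forms and spreadsheet oracle", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 0, 1, 1, 0, 1, 0, 1)
  sv <- survival_response(paste0("s", 1:8), time, event)
  G <- km_censoring(sv)

  # BS(0) = 0 when S(0) = 1
  expect_equal(brier_score(0, sv, rep(1, 8), G), 0)

  # no censoring, S = 0.5 -> 0.25
  sv_nc <- survival_response(paste0("s", 1:8), time, rep(1L, 8))
  G_nc <- km_censoring(sv_nc)
  expect_equal(brier_score(3.5, sv_nc, rep(0.5, 8), G_nc), 0.25)

  # spreadsheet-style evaluation of the IPCW formula with censoring
  set.seed(75)
  S_hat <- runif(8)
  t0 <- 4.5
  oracle <- 0
  for (i in 1:8) {
    if (time[i] <= t0 && event[i] == 1) {
      oracle <- oracle + S_hat[i]^2 / oracle_km(time, 1 - event, time[i] - 1e-9)
    } else if (time[i] > t0) {
      oracle <- oracle + (1 - S_hat[i])^2 / oracle_km(time, 1 - event, t0)
    }
  }
  expect_equal(brier_score(t0, sv, S_hat, G), oracle / 8)

  # null model on uncensored data: BS equals the binomial variance term
  p_hat <- mean(time > t0)
  expect_equal(brier_score(t0, sv_nc, rep(p_hat, 8), G_nc), p_hat * (1 - p_hat))

  # perfect oracle predictions on uncensored data -> BS = 0
  S_perfect <- as.numeric(time > t0)
  expect_equal(brier_score(t0, sv_nc, S_perfect, G_nc), 0)
})

test_that("integrated Brier score: constants, linear ramp, step refinement", {
  const <- list(time = seq(0, 10, by = 0.5), bs = rep(0.2, 21))
  expect_equal(integrated_brier_score(const, 10), 0.2)

  dense <- seq(0, 10, length.out = 2001)
  lin <- list(time = dense, bs = dense / 10)
  expect_equal(integrated_brier_score(lin, 10), 0.5, tolerance = 1e-6)

  # piecewise-constant curve: grid refinement inside segments changes nothing
  step_curve <- list(time = c(0, 2, 2, 6, 6, 10), bs = c(0.1, 0.1, 0.3, 0.3, 0.2, 0.2))
  ibs <- integrated_brier_score(step_curve, 10)
  oracle <- (2 * 0.1 + 4 * 0.3 + 4 * 0.2) / 10
  expect_equal(ibs, oracle)
  refined <- list(time = c(0, 1, 2, 2, 4, 6, 6, 8, 10),
                  bs = c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3, 0.2, 0.2, 0.2))
  expect_equal(integrated_brier_score(refined, 10), ibs)

  # curve shorter than t*: carried forward
  short <- list(time = c(0, 5), bs = c(0, 0.5))
  expect_equal(integrated_brier_score(short, 10), (0.25 * 5 + 0.5 * 5) / 10)
})

test_that("prediction error curves average pointwise across splits", {
  c1 <- structure(list(time = c(0, 1, 2), bs = c(0, 0.1, 0.2)),
                  class = "PredictionErrorCurve")
  expect_equal(prediction_error_curve(list(c1)), c1, ignore_attr = TRUE)
  expect_equal(prediction_error_curve(list(c1, c1))$bs, c1$bs)
  # distinct grids: step interpolation then mean, against direct recomputation
  c2 <- structure(list(time = c(0, 1.5, 2.5), bs = c(0.05, 0.15, 0.3)),
                  class = "PredictionErrorCurve")
  avg <- prediction_error_curve(list(c1, c2))
  grid <- sort(unique(c(c1$time, c2$time)))
  v1 <- sapply(grid, function(t) c1$bs[max(which(c1$time <= t))])
  v2 <- sapply(grid, function(t) c2$bs[max(which(c2$time <= t))])
  expect_equal(avg$time, grid)
  expect_equal(avg$bs, (v1 + v2) / 2)
  expect_error(prediction_error_curve(list()), "no curves")
})
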