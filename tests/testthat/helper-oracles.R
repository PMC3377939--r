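# Independent oracles and small fixture builders shared across the suite.
# Oracles are deliberately naive (enumeration / direct formulas) and never
# call the package's own computational path.

# brute-force PAM: enumerate all C(N, K) medoid subsets
oracle_pam_objective <- function(d, K) {
  combs <- utils::combn(nrow(d), K)
  min(apply(combs, 2, function(s) sum(apply(d[, s, drop = FALSE], 1, min))))
}

# direct Breslow log partial likelihood by explicit risk-set enumeration
oracle_loglik <- function(eta, time, event) {
  sum(vapply(which(event == 1), function(i) {
    eta[i] - log(sum(exp(eta[time >= time[i]])))
  }, numeric(1)))
}

# Kaplan-Meier product-limit by hand (events given by `status`)
oracle_km <- function(time, status, at) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  for (u in ut[ut <= at]) {
    n_at <- sum(time >= u)
    d <- sum(time == u & status == 1)
    s <- s * (1 - d / n_at)
  }
  s
}

# Independent Newton-Raphson maximizer of the Breslow log partial likelihood,
# written from the per-event-time sums directly (no shared code with the
# package's cumulative-sum implementation).
oracle_newton <- function(XX, time, event, maxit = 50) {
  P <- ncol(XX)
  theta <- numeric(P)
  for (it in seq_len(maxit)) {
    eta <- drop(XX %*% theta)
    e <- exp(eta)
    grad <- numeric(P)
    H <- matrix(0, P, P)
    for (u in sort(unique(time[event == 1]))) {
      risk <- which(time >= u)
      dk <- sum(time == u & event == 1)
      s0 <- sum(e[risk])
      s1 <- colSums(e[risk] * XX[risk, , drop = FALSE])
      s2 <- crossprod(XX[risk, , drop = FALSE], e[risk] * XX[risk, , drop = FALSE])
      xbar <- s1 / s0
      grad <- grad - dk * xbar
      H <- H - dk * (s2 / s0 - tcrossprod(xbar))
    }
    grad <- grad + colSums(XX[event == 1, , drop = FALSE])
    step <- solve(-H + diag(1e-10, P), grad)
    theta <- theta + step
    if (max(abs(grad)) < 1e-10) break
  }
  theta
}

# random survival data generator for Cox-core tests
make_surv_data <- function(n, p = 3, q = 1, beta = NULL, gamma = NULL,
                           base_rate = 0.1, cens_rate = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  Z <- if (q > 0) {
    matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("z", seq_len(q))))
  } else NULL
  beta <- beta %||% rep(0, p)
  gamma <- gamma %||% rep(0, q)
  eta <- drop(X %*% beta) + (if (q > 0) drop(Z %*% gamma) else 0)
  tt <- rexp(n, base_rate * exp(eta))
  cc <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  sv <- survival_response(sprintf("s%03d", seq_len(n)), pmin(tt, cc),
                          as.integer(tt <= cc))
  list(input = risk_model_input(X, Z, sv), X = X, Z = Z, survival = sv,
       beta = beta, gamma = gamma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny deterministic expression matrix fixture
toy_expression <- function(genes = 3, samples = 5, seed = 7) {
  set.seed(seed)
  m <- matrix(round(rnorm(genes * samples), 4), genes, samples,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("s", seq_len(samples))))
  expression_matrix(m)
}

# fully assembled toy dataset with two 3-gene groups
toy_dataset <- function(n = 30, seed = 11) {
  set.seed(seed)
  expr <- matrix(rnorm(6 * n), 6, n,
                 dimnames = list(paste0("g", 1:6), paste0("s", seq_len(n))))
  groups <- gene_group_map(list("GO:A" = paste0("g", 1:3), "GO:B" = paste0("g", 4:6)))
  surv <- survival_response(colnames(expr), rexp(n, 0.2) + 0.01,
                            rbinom(n, 1, 0.7))
  clin <- clinical_covariates(colnames(expr),
                              cbind(age = rnorm(n), grade = rbinom(n, 1, 0.5)))
  assemble_dataset(expression_matrix(expr), surv, clin, groups)
}
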