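# Independent oracles used across the test files. Each reimplements the
# quantity under test by a different route than the package (brute force,
# general-purpose optimization, closed form) so agreement is evidence,
# not tautology.

# Mean logistic negative log-likelihood by naive per-row summation.
oracle_logistic_loss <- function(intercept, coefs, X, y, offset = NULL) {
  eta <- intercept + as.vector(X %*% coefs)
  if (!is.null(offset)) eta <- eta + offset
  p <- 1 / (1 + exp(-eta))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# General-purpose convex solver for the centered L1 logistic objective:
# split beta - c = u - v with u, v >= 0 and minimize the smooth function
# (1/n) sum nll + lambda * sum(u + v) by box-constrained L-BFGS-B.
# Exact at the kink because the active bounds are u = v = 0.
oracle_penalized_fit <- function(X, y, lambda, center = NULL, offset = NULL,
                                 maxit = 2000) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(center)) center <- rep(0, p)
  if (is.null(offset)) offset <- rep(0, n)
  fn <- function(par) {
    b0 <- par[1]; u <- par[2:(p + 1)]; v <- par[(p + 2):(2 * p + 1)]
    beta <- center + u - v
    eta <- b0 + as.vector(X %*% beta) + offset
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(u + v)
  }
  gr <- function(par) {
    b0 <- par[1]; u <- par[2:(p + 1)]; v <- par[(p + 2):(2 * p + 1)]
    beta <- center + u - v
    eta <- b0 + as.vector(X %*% beta) + offset
    resid <- 1 / (1 + exp(-eta)) - y
    gbeta <- as.vector(crossprod(X, resid)) / n
    c(mean(resid), gbeta + lambda, -gbeta + lambda)
  }
  fit <- stats::optim(par = rep(0, 2 * p + 1), fn = fn, gr = gr,
                      method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, 2 * p)),
                      control = list(maxit = maxit, factr = 10))
  b0 <- fit$par[1]
  u <- fit$par[2:(p + 1)]; v <- fit$par[(p + 2):(2 * p + 1)]
  list(intercept = b0, coefficients = center + u - v, value = fit$value)
}

# AUC by exhaustive positive x negative pair counting, ties worth 1/2.
oracle_auc_pairs <- function(y, s) {
  sp <- s[y == 1]; sn <- s[y == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# A small single-stratum synthetic study used by several files.
tiny_study <- function(seed, n_source = 800, n_target = 200, p = 21,
                       sparsity_delta = 3, delta_mag = 0.5,
                       proxy_fraction = 0, missing_rate = 0) {
  cfg <- synthetic_config(
    n_source = n_source, n_target = n_target, p_predictors = p,
    sparsity_beta = 6, sparsity_delta = sparsity_delta,
    delta_magnitude_by_stratum = c(White = delta_mag, Black = 0.8,
                                   Hispanic = 0.5),
    proxy_fraction = proxy_fraction, missing_rate = missing_rate,
    stratum_proportions = c(White = 1), seed = seed)
  params <- generate_true_parameters(cfg, probe_n = 20000)
  cohorts <- generate_cohorts(cfg, params)
  list(cfg = cfg, params = params, source = cohorts$source,
       target = cohorts$target)
}

# Random small matrices for solver tests.
random_instance <- function(seed, n = 120, p = 8, separation = 0.8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- rnorm(p, 0, separation) * rbinom(p, 1, 0.6)
  y <- rbinom(n, 1, plogis(0.3 + X %*% beta))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}
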