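# Penalized logistic core: loss oracle, solver limits and oracle
# equivalence, cross-validation behavior, path properties.

test_that("logistic loss matches closed forms and a naive summation", {
  set.seed(1)
  n <- 50; p <- 6
  X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("x", 1:p)
  y <- rep(c(0, 1), length.out = n)
  b0 <- coef_vector(0, setNames(rep(0, p), colnames(X)))
  expect_equal(logistic_loss(b0, X, y), log(2), tolerance = 1e-12)
  beta <- coef_vector(0.3, setNames(rnorm(p), colnames(X)))
  expect_equal(logistic_loss(beta, X, y),
               oracle_logistic_loss(0.3, beta$coefficients, X, y),
               tolerance = 1e-12)
  off <- rnorm(n)
  expect_equal(logistic_loss(beta, X, y, offset = off),
               oracle_logistic_loss(0.3, beta$coefficients, X, y, off),
               tolerance = 1e-12)
  # perfect separation drives the loss to (numerically) zero, stably
  Xsep <- X
  Xsep[, 1] <- ifelse(X[, 1] > 0, 1, -1)
  eta_big <- coef_vector(0, setNames(c(690, rep(0, p - 1)), colnames(X)))
  ysep <- as.numeric(Xsep[, 1] > 0)
  expect_lt(logistic_loss(eta_big, Xsep, ysep), 1e-10)
  expect_true(is.finite(logistic_loss(eta_big, Xsep, ysep)))
  expect_error(logistic_loss(beta, X, y + 0.5), "binary")
})

test_that("lambda = 0 reproduces the unpenalized MLE", {
  inst <- random_instance(7, n = 150, p = 6)
  fit <- fit_lasso_logistic(inst$X, inst$y, 0)
  mle <- glm(inst$y ~ inst$X, family = binomial())
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - coef(mle))), 1e-4)
})

test_that("a huge penalty shrinks exactly to the center", {
  inst <- random_instance(8, n = 150, p = 6)
  # center zero: null model, intercept = logit of the prevalence
  fit0 <- fit_lasso_logistic(inst$X, inst$y, 1e6)
  expect_true(all(fit0$coefficients == 0))
  expect_lt(abs(fit0$intercept - qlogis(mean(inst$y))), 1e-6)
  # nonzero center: coefficients collapse onto it
  ctr <- setNames(rnorm(ncol(inst$X), 0, 0.5), colnames(inst$X))
  fitc <- fit_lasso_logistic(inst$X, inst$y, 1e6, penalty_center = ctr)
  expect_lt(max(abs(fitc$coefficients - ctr)), 1e-6)
})

test_that("solver matches a general convex solver and glmnet", {
  skip_if_not_installed("glmnet")
  for (seed in c(11, 12)) {
    inst <- random_instance(seed, n = 200, p = 10)
    for (lam in c(0.01, 0.05)) {
      fit <- fit_lasso_logistic(inst$X, inst$y, lam)
      ora <- oracle_penalized_fit(inst$X, inst$y, lam)
      expect_lt(max(abs(fit$coefficients - ora$coefficients)), 1e-4)
      g <- glmnet::glmnet(inst$X, inst$y, family = "binomial", lambda = lam,
                          standardize = FALSE, thresh = 1e-13)
      expect_lt(max(abs(fit$coefficients - as.numeric(g$beta))), 1e-4)
    }
    # with a penalty center and an extra offset
    ctr <- setNames(rnorm(10, 0, 0.4), colnames(inst$X))
    off <- rnorm(200, 0, 0.3)
    fit <- fit_lasso_logistic(inst$X, inst$y, 0.05, penalty_center = ctr,
                              offset = off)
    ora <- oracle_penalized_fit(inst$X, inst$y, 0.05, center = ctr,
                                offset = off)
    expect_lt(max(abs(fit$coefficients - ora$coefficients)), 1e-4)
    expect_lt(abs(fit$intercept - ora$intercept), 1e-4)
  }
})

test_that("objective trace is monotone non-increasing", {
  for (seed in c(21, 22, 23)) {
    inst <- random_instance(seed)
    fit <- fit_lasso_logistic(inst$X, inst$y, 0.02)
    expect_true(all(diff(attr(fit, "trace")) <= 1e-12))
  }
})

test_that("nonzero deviations are non-increasing along the penalty path", {
  inst <- random_instance(30, n = 200, p = 10, separation = 0.5)
  grid <- lambda_grid(inst$X, inst$y, n_lambda = 20, min_ratio = 1e-3)
  nz <- vapply(grid, function(l)
    sum(abs(fit_lasso_logistic(inst$X, inst$y, l)$coefficients) > 1e-10), 0L)
  violations <- sum(diff(rev(nz)) > 0) # rev: increasing lambda
  expect_lte(violations, 1)
})

test_that("cross-validation selects sensibly and reproducibly", {
  inst <- random_instance(40, n = 200, p = 8, separation = 1)
  # one-value grid is returned as-is
  one <- cv_select_lambda(inst$X, inst$y, K = 5, lambda_grid = 0.07, seed = 1)
  expect_equal(one$lambda, 0.07)
  # same seed, same folds and selection
  a <- cv_select_lambda(inst$X, inst$y, K = 10, seed = 99)
  b <- cv_select_lambda(inst$X, inst$y, K = 10, seed = 99)
  expect_identical(a, b)
  # at the largest (fully shrunk) grid value the CV loss is the null
  # entropy of the prevalence
  pi_hat <- mean(inst$y)
  null_loss <- -(pi_hat * log(pi_hat) + (1 - pi_hat) * log(1 - pi_hat))
  expect_lt(abs(a$cv_trace$loss[1] - null_loss), 0.05)
  # and the selected value beats the null model
  expect_lt(min(a$cv_trace$loss), null_loss)
})

test_that("degenerate outcomes are rejected or reduce K with a warning", {
  inst <- random_instance(50, n = 60, p = 5)
  y_rare <- c(rep(1, 4), rep(0, 56))
  expect_warning(cv_select_lambda(inst$X, y_rare, K = 10, seed = 1),
                 "reducing K")
  expect_error(cv_select_lambda(inst$X, rep(0, 60), K = 10, seed = 1),
               "single class")
})
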