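# Performance measures: hand values, brute-force oracles, invariances,
# large-sample calibration identities.

test_that("Brier score matches hand evaluation and its constant-prediction form", {
  expect_equal(brier(c(1, 0), c(1, 0)), 0)
  expect_equal(brier(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_equal(brier(c(1, 1, 0), c(0.8, 0.4, 0.2)), 0.44 / 3,
               tolerance = 1e-12)
  # constant prediction c: pi (1-c)^2 + (1-pi) c^2, minimized at c = pi
  set.seed(2)
  y <- rbinom(400, 1, 0.3)
  pi_hat <- mean(y)
  for (cc in c(0.1, 0.3, 0.5, 0.9)) {
    expect_equal(brier(y, rep(cc, 400)),
                 pi_hat * (1 - cc)^2 + (1 - pi_hat) * cc^2,
                 tolerance = 1e-12)
  }
  vals <- vapply(seq(0.05, 0.95, by = 0.05),
                 function(cc) brier(y, rep(cc, 400)), 0)
  expect_equal(seq(0.05, 0.95, by = 0.05)[which.min(vals)], pi_hat,
               tolerance = 0.05)
  expect_error(brier(numeric(0), numeric(0)), "empty")
})

test_that("AUC equals exhaustive pair counting, with ties worth one half", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  set.seed(3)
  for (i in 1:25) {
    n <- sample(20:100, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
    expect_equal(auc(y, s), oracle_auc_pairs(y, s), tolerance = 1e-12)
  }
  expect_error(auc(rep(1, 5), rnorm(5)), "auc")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  y <- rbinom(200, 1, 0.4)
  s <- rnorm(200)
  base <- auc(y, s)
  expect_equal(auc(y, exp(s)), base, tolerance = 1e-12)
  expect_equal(auc(y, 3 * s - 7), base, tolerance = 1e-12)
  expect_equal(auc(y, rank(s, ties.method = "average")), base,
               tolerance = 1e-12)
})

test_that("average precision handles blocks of ties and known rankings", {
  expect_equal(auprc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # single positive ranked last among four
  expect_equal(auprc(c(0, 0, 0, 1), c(0.9, 0.8, 0.7, 0.1)), 0.25)
  # all tied: one block, precision = prevalence at full recall
  expect_equal(auprc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  # random ranker baseline is the prevalence
  set.seed(5)
  n <- 1e5
  y <- rbinom(n, 1, 0.15)
  s <- runif(n)
  expect_lt(abs(auprc(y, s) - mean(y)), 0.05)
  expect_error(auprc(rep(0, 5), rnorm(5)), "positive")
})

test_that("calibration recovers truth, offsets, and flat association", {
  set.seed(6)
  n <- 1e5
  lp <- rnorm(n, -1.5, 1.2)
  p <- plogis(lp)
  y <- rbinom(n, 1, p)
  cal <- calibration(y, p)
  expect_lt(abs(cal$intercept), 0.05)
  expect_gt(cal$slope, 0.95); expect_lt(cal$slope, 1.05)
  # doubling the odds shifts the intercept by -log 2
  cal2 <- calibration(y, plogis(lp + log(2)))
  expect_lt(abs(cal2$intercept + log(2)), 0.05)
  # predictions independent of the outcome: slope near zero
  cal3 <- calibration(y, plogis(rnorm(n, -1.5, 1.2)))
  expect_lt(abs(cal3$slope), 0.05)
  # constant predictions: intercept computed, slope undefined
  expect_warning(cal4 <- calibration(y, rep(0.2, n)), "constant")
  expect_true(is.na(cal4$slope))
  expect_equal(cal4$intercept, qlogis(mean(y)) - qlogis(0.2),
               tolerance = 0.05)
})

test_that("metric bounds hold across a fuzz suite", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    p <- runif(n)
    b <- brier(y, p)
    expect_true(b >= 0 && b <= 1)
    if (length(unique(y)) == 2) {
      a <- auc(y, p)
      expect_true(a >= 0 && a <= 1)
    }
    if (any(y == 1)) {
      ap <- auprc(y, p)
      expect_true(ap >= 0 && ap <= 1)
    }
  }
})
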