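# L1-penalized logistic regression with an optional penalty center:
#   min_beta (1/n) sum_i nll(beta; x_i, y_i) + lambda * ||beta - c||_1
# (intercept unpenalized). Solved by reparameterizing delta = beta - c
# and fitting a standard L1 logistic problem with fixed offset X c in
# compiled code (proximal Newton + coordinate descent, monotone
# objective trace).

#' Coefficient vector of a fitted logistic model
#'
#' @param intercept scalar intercept.
#' @param coefficients named numeric vector aligned to model-matrix
#'   columns.
#' @param lambda penalty strength the fit used (`NA` for unpenalized).
#' @param scale_context encoding statistics under which the fit was made
#'   (see [encode()]), or `NULL`.
#' @return object of class `coef_vector`.
#' @export
coef_vector <- function(intercept, coefficients, lambda = NA_real_,
                        scale_context = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)))
  if (!all(is.finite(c(intercept, coefficients))))
    stop("coef_vector: non-finite entries", call. = FALSE)
  structure(list(intercept = unname(intercept), coefficients = coefficients,
                 lambda = lambda, scale_context = scale_context),
            class = "coef_vector")
}

#' @export
print.coef_vector <- function(x, ...) {
  nz <- sum(abs(x$coefficients) > 1e-10)
  cat(sprintf("<coef_vector: intercept %.4f, %d/%d nonzero coefficients%s>\n",
              x$intercept, nz, length(x$coefficients),
              if (is.na(x$lambda)) "" else sprintf(", lambda %.4g", x$lambda)))
  invisible(x)
}

as_center <- function(penalty_center, X) {
  p <- ncol(X)
  if (is.null(penalty_center)) return(rep(0, p))
  cvec <- if (inherits(penalty_center, "coef_vector"))
    penalty_center$coefficients else penalty_center
  if (length(cvec) != p)
    stop("penalty_center length does not match ncol(X)", call. = FALSE)
  if (!is.null(names(cvec)) && !is.null(colnames(X)) &&
      !identical(names(cvec), colnames(X))) {
    d <- c(setdiff(names(cvec), colnames(X)), setdiff(colnames(X), names(cvec)))
    if (length(d))
      stop("penalty_center misaligned with X columns: ",
           paste(d, collapse = ", "), call. = FALSE)
    cvec <- cvec[colnames(X)]
  }
  unname(cvec)
}

check_binary <- function(y) {
  if (!is.numeric(y) || any(!(y %in% c(0, 1))))
    stop("y must be a binary 0/1 vector", call. = FALSE)
  as.numeric(y)
}

#' Mean logistic negative log-likelihood
#'
#' Mean over rows of `-[y log(sigma(eta)) + (1 - y) log(1 - sigma(eta))]`
#' with `eta = intercept + X %*% coefficients + offset`; numerically
#' stable for |eta| up to and beyond 700.
#'
#' @param beta a [coef_vector()] (or list with `intercept` and
#'   `coefficients`).
#' @param X numeric model matrix.
#' @param y binary 0/1 outcome vector.
#' @param offset optional per-row additive term on the logit scale.
#' @return nonnegative scalar.
#' @export
logistic_loss <- function(beta, X, y, offset = NULL) {
  y <- check_binary(y)
  stopifnot(nrow(X) == length(y))
  co <- beta$coefficients
  if (length(co) != ncol(X))
    stop("coefficient length does not match ncol(X)", call. = FALSE)
  eta <- beta$intercept + drop(X %*% unname(co))
  if (!is.null(offset)) eta <- eta + offset
  mean(log1pexp(eta) - y * eta)
}

# log(1 + exp(x)), stable
log1pexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 35
  lo <- x < -35
  mid <- !hi & !lo
  out[hi] <- x[hi] + exp(-x[hi])
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out
}

#' Fit an L1-penalized logistic regression, optionally centered
#'
#' Minimizes `(1/n) sum_i nll(beta) + lambda * ||beta - c||_1` with an
#' unpenalized intercept, where `c` is the penalty center (zero when
#' absent — ordinary LASSO; the source coefficient vector in the transfer
#' step). Solved via `delta = beta - c` as a standard L1 problem with
#' fixed offset `X %*% c`.
#'
#' @param X numeric model matrix (columns named).
#' @param y binary 0/1 outcome.
#' @param lambda nonnegative penalty strength.
#' @param penalty_center optional [coef_vector()] or numeric p-vector.
#' @param offset optional additional per-row logit offset.
#' @param tol relative-objective convergence tolerance.
#' @param max_iter maximum outer (proximal Newton) iterations.
#' @param init optional warm-start `coef_vector`.
#' @return a [coef_vector()] with attributes `objective`, `trace`
#'   (per-iteration objective values, non-increasing), `converged`.
#' @export
fit_lasso_logistic <- function(X, y, lambda, penalty_center = NULL,
                               offset = NULL, tol = 1e-8, max_iter = 1000,
                               init = NULL) {
  y <- check_binary(y)
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cvec <- as_center(penalty_center, X)
  off <- drop(X %*% cvec)
  if (!is.null(offset)) off <- off + offset
  if (is.null(init)) {
    ybar <- min(max(mean(y), 1e-12), 1 - 1e-12)
    b0 <- qlogis(ybar) - mean(off)
    d0 <- rep(0, ncol(X))
    # homotopy warm-up: a short decreasing-penalty path down to lambda
    # makes cold fits at small penalties as cheap as warm ones
    lmax <- lambda_max(X, y, penalty_center, offset)
    if (lambda > 0 && is.finite(lmax) && lmax > lambda * 1.5) {
      warm_grid <- exp(seq(log(lmax), log(lambda), length.out = 8))[-8]
      wp <- .cd_lasso_path(X, y, warm_grid, off, tol = max(tol, 1e-6))
      b0 <- wp[1, ncol(wp)]
      d0 <- wp[-1, ncol(wp)]
    }
  } else {
    d0 <- unname(init$coefficients) - cvec
    b0 <- init$intercept
  }
  fit <- .cd_lasso_logistic(X, y, lambda, off, d0, b0,
                            tol = tol, max_outer = max_iter)
  if (!fit$converged)
    stop(sprintf(paste0("fit_lasso_logistic did not converge within %d ",
                        "iterations (last objectives: %s)"),
                 max_iter,
                 paste(signif(utils::tail(fit$trace, 3), 8), collapse = ", ")),
         call. = FALSE)
  beta <- cvec + drop(fit$delta)
  names(beta) <- colnames(X)
  out <- coef_vector(fit$b0, beta, lambda = lambda)
  attr(out, "objective") <- fit$objective
  attr(out, "trace") <- fit$trace
  attr(out, "converged") <- fit$converged
  out
}

# Smallest lambda shrinking all penalized coordinates to the center:
# max_j |(1/n) X_j' (mu - y)| at the centered null model (intercept-only
# given offset X c).
lambda_max <- function(X, y, penalty_center = NULL, offset = NULL) {
  y <- check_binary(y)
  X <- as.matrix(X)
  cvec <- as_center(penalty_center, X)
  off <- drop(X %*% cvec)
  if (!is.null(offset)) off <- off + offset
  b0 <- 0
  for (i in 1:100) { # 1-D Newton for the intercept
    mu <- plogis(b0 + off)
    g <- mean(mu - y)
    h <- mean(mu * (1 - mu))
    if (h < 1e-12) break
    step <- g / h
    b0 <- b0 - step
    if (abs(step) < 1e-12) break
  }
  mu <- plogis(b0 + off)
  max(abs(drop(crossprod(X, mu - y))) / nrow(X))
}

#' Default penalty grid
#'
#' 100 log-spaced values from the data-derived `lambda_max` (smallest
#' penalty with an all-zero penalized part) down to `1e-4 * lambda_max`.
#'
#' @inheritParams fit_lasso_logistic
#' @param n_lambda grid length.
#' @param min_ratio ratio of smallest to largest grid value.
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, penalty_center = NULL, offset = NULL,
                        n_lambda = 100, min_ratio = 1e-4) {
  lmax <- lambda_max(X, y, penalty_center, offset)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

# Stratified K-fold assignment (both classes in every fold when
# possible). When `groups` is given (e.g. original row identities of a
# bootstrap resample), all rows of a group share a fold, so duplicated
# rows never straddle a train/test split.
stratified_folds <- function(y, K, seed, groups = NULL) {
  if (is.null(groups)) groups <- seq_along(y)
  gid <- match(groups, unique(groups))
  gy <- y[!duplicated(gid)]
  with_seed(seed, {
    gfold <- integer(length(gy))
    for (cls in unique(gy)) {
      idx <- sample(which(gy == cls))
      gfold[idx] <- rep_len(seq_len(K), length(idx))
    }
    gfold[gid]
  })
}

#' Select the penalty by stratified K-fold cross-validation
#'
#' Partitions rows into K folds stratified by outcome, fits the full
#' penalty path on each training split (warm starts), and scores each
#' penalty by the mean held-out logistic negative log-likelihood. The
#' selected penalty is the grid arg-min; exact ties break towards the
#' larger (more regularized) value.
#'
#' @inheritParams fit_lasso_logistic
#' @param K number of folds (default 10). If the rarer class has fewer
#'   than K members, K is reduced to that count with a warning; a
#'   single-class outcome is an error.
#' @param lambda_grid decreasing penalty grid; derived from the data via
#'   [lambda_grid()] when `NULL`.
#' @param seed integer seed fixing the fold assignment.
#' @param groups optional per-row identities (e.g. original row ids of a
#'   bootstrap resample); rows sharing an identity are assigned to the
#'   same fold, so duplicates cannot leak between training and held-out
#'   folds.
#' @return list with `lambda` (selected value), `cv_trace` (data frame of
#'   per-penalty mean held-out loss), `K`, and `fold` assignments.
#' @export
cv_select_lambda <- function(X, y, K = 10, lambda_grid = NULL,
                             penalty_center = NULL, offset = NULL,
                             seed = 1L, tol = 1e-5, groups = NULL) {
  y <- check_binary(y)
  X <- as.matrix(X)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("cv_select_lambda: outcome has a single class", call. = FALSE)
  if (!is.null(groups)) {
    gid <- match(groups, unique(groups))
    gy <- y[!duplicated(gid)]
    n1 <- sum(gy == 1); n0 <- sum(gy == 0)
  }
  mc <- min(n1, n0)
  if (mc < K) {
    warning(sprintf("cv_select_lambda: rare class has %d rows; reducing K from %d to %d",
                    mc, K, mc))
    K <- mc
  }
  if (K < 2) stop("cv_select_lambda: need K >= 2", call. = FALSE)
  if (is.null(lambda_grid))
    lambda_grid <- demtransfer::lambda_grid(X, y, penalty_center, offset)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  cvec <- as_center(penalty_center, X)
  off_c <- drop(X %*% cvec)
  off <- if (is.null(offset)) rep(0, nrow(X)) else offset
  fold <- stratified_folds(y, K, seed, groups = groups)
  losses <- matrix(NA_real_, nrow = length(lambda_grid), ncol = K)
  for (k in seq_len(K)) {
    tr <- fold != k
    losses[, k] <- .cd_cv_fold(X[tr, , drop = FALSE], y[tr],
                               X[!tr, , drop = FALSE], y[!tr],
                               lambda_grid, off_c[tr] + off[tr],
                               off_c[!tr] + off[!tr], tol = tol)
  }
  cv_mean <- rowMeans(losses)
  best <- which.min(cv_mean) # grid is decreasing: first min = largest lambda
  list(lambda = lambda_grid[best],
       cv_trace = data.frame(lambda = lambda_grid, loss = cv_mean),
       K = K, fold = fold)
}
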