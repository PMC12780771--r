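# Transfer step: refit the source coefficients on the target cohort
# under an L1 penalty on the coefficient deviation, and guard against
# negative transfer.

#' Fit a source-knowledge logistic LASSO
#'
#' Step one of the transfer procedure: a standard logistic LASSO on the
#' (dichotomized) source outcome, with the penalty chosen by stratified
#' K-fold cross-validation.
#'
#' @inheritParams cv_select_lambda
#' @param tol convergence tolerance of the final fit (cohort-scale fits
#'   use a looser tolerance than the solver's single-fit default).
#' @return a [coef_vector()] carrying the selected `lambda` and, as
#'   attribute `cv_trace`, the cross-validation trace.
#' @export
fit_source_lasso <- function(X, y, K = 10, lambda_grid = NULL, seed = 1L,
                             tol = 1e-6) {
  cv <- cv_select_lambda(X, y, K = K, lambda_grid = lambda_grid, seed = seed)
  fit <- fit_lasso_logistic(X, y, cv$lambda, tol = tol)
  attr(fit, "cv_trace") <- cv$cv_trace
  fit
}

#' Transfer fit: deviation-penalized refit on the target cohort
#'
#' Step two of the transfer procedure. With the source estimate
#' `beta_source` as penalty center, selects the deviation penalty by
#' stratified K-fold cross-validation on the target data and refits at
#' the selected value. The fitted deviation `delta = beta_tl - beta_source`
#' is sparse: only predictors whose association with the outcome genuinely
#' differs between cohorts move away from the source value.
#'
#' @param target_X,target_y target model matrix (columns named,
#'   identical set to the source fit's) and binary outcome.
#' @param beta_source source [coef_vector()].
#' @param tol convergence tolerance of the final fit.
#' @inheritParams cv_select_lambda
#' @param groups optional per-row identities for leak-free fold
#'   assignment on bootstrap resamples (see [cv_select_lambda()]).
#' @return object of class `transfer_fit` with `beta_source`, `beta_tl`,
#'   `delta`, the selected penalties, CV traces, and a `transferable`
#'   slot (`NA` until [detect_transferability()] is consulted).
#' @export
fit_transfer <- function(target_X, target_y, beta_source, K = 10,
                         lambda_grid = NULL, seed = 1L, tol = 1e-6,
                         groups = NULL) {
  stopifnot(inherits(beta_source, "coef_vector"))
  tx_names <- colnames(target_X)
  src_names <- names(beta_source$coefficients)
  if (!identical(sort(tx_names), sort(src_names))) {
    d <- c(setdiff(tx_names, src_names), setdiff(src_names, tx_names))
    stop("fit_transfer: target and source predictor columns differ: ",
         paste(d, collapse = ", "), call. = FALSE)
  }
  cv <- cv_select_lambda(target_X, target_y, K = K,
                         lambda_grid = lambda_grid,
                         penalty_center = beta_source, seed = seed,
                         groups = groups)
  beta_tl <- fit_lasso_logistic(target_X, target_y, cv$lambda,
                                penalty_center = beta_source, tol = tol)
  delta <- beta_tl$coefficients - beta_source$coefficients[tx_names]
  structure(list(beta_source = beta_source, beta_tl = beta_tl,
                 delta = delta,
                 lambda_source = beta_source$lambda,
                 lambda_transfer = cv$lambda,
                 cv_trace_source = attr(beta_source, "cv_trace"),
                 cv_trace_transfer = cv$cv_trace,
                 transferable = NA),
            class = "transfer_fit")
}

#' @export
print.transfer_fit <- function(x, ...) {
  cat(sprintf(paste0("<transfer_fit: %d/%d nonzero deviations, ",
                     "lambda_transfer %.4g, transferable: %s>\n"),
              sum(abs(x$delta) > 1e-10), length(x$delta),
              x$lambda_transfer, format(x$transferable)))
  invisible(x)
}

#' Predicted probabilities from a fitted coefficient vector
#'
#' @param object a [coef_vector()] or [transfer_fit()] (uses `beta_tl`).
#' @param X model matrix with matching columns.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.coef_vector <- function(object, X, ...) {
  co <- object$coefficients
  if (!is.null(colnames(X)) && !identical(colnames(X), names(co)))
    co <- co[colnames(X)]
  plogis(object$intercept + drop(as.matrix(X) %*% unname(co)))
}

#' @rdname predict.coef_vector
#' @export
predict.transfer_fit <- function(object, X, ...) predict(object$beta_tl, X)

#' Negative-transfer guard
#'
#' Decides whether borrowing from the source helps target prediction.
#' The target rows are split into K stratified folds; on each training
#' split both a target-only LASSO and a transfer fit (centered at the
#' full-source estimate) are tuned and fitted, and both are scored on the
#' held-out fold by mean logistic loss. The source is declared
#' transferable when
#' `mean(loss_transfer) <= mean(loss_target_only) + threshold_c * sd(loss_target_only)`
#' (SD across folds), i.e. transfer is allowed unless it is worse than
#' target-only by more than `threshold_c` fold-SDs.
#'
#' @param source_X,source_y source model matrix and (dichotomized) binary
#'   outcome; ignored when `beta_source` is supplied.
#' @param target_X,target_y target model matrix and outcome.
#' @param K folds (default 10).
#' @param threshold_c slack in units of the fold-to-fold SD (default 1;
#'   `Inf` always transfers).
#' @param seed integer seed.
#' @param beta_source optional precomputed source [coef_vector()].
#' @return logical; attributes `loss_transfer` and `loss_target_only`
#'   hold the per-fold held-out losses.
#' @export
detect_transferability <- function(source_X, source_y, target_X, target_y,
                                   K = 10, threshold_c = 1, seed = 1L,
                                   beta_source = NULL) {
  target_y <- check_binary(target_y)
  if (is.null(beta_source))
    beta_source <- fit_source_lasso(source_X, source_y, K = K,
                                    seed = child_seed(seed, 91L))
  mc <- min(sum(target_y == 1), sum(target_y == 0))
  if (mc == 0)
    stop("detect_transferability: target outcome has a single class",
         call. = FALSE)
  if (mc < K) {
    warning(sprintf("detect_transferability: reducing K from %d to %d", K, mc))
    K <- mc
  }
  fold <- stratified_folds(target_y, K, child_seed(seed, 92L))
  loss_to <- loss_tl <- numeric(K)
  for (k in seq_len(K)) {
    tr <- fold != k
    Xtr <- target_X[tr, , drop = FALSE]; ytr <- target_y[tr]
    Xte <- target_X[!tr, , drop = FALSE]; yte <- target_y[!tr]
    cv_to <- cv_select_lambda(Xtr, ytr, K = min(K, 5),
                              seed = child_seed(seed, 100L + k))
    fit_to <- fit_lasso_logistic(Xtr, ytr, cv_to$lambda, tol = 1e-6)
    tf <- fit_transfer(Xtr, ytr, beta_source, K = min(K, 5),
                       seed = child_seed(seed, 200L + k))
    loss_to[k] <- logistic_loss(fit_to, Xte, yte)
    loss_tl[k] <- logistic_loss(tf$beta_tl, Xte, yte)
  }
  s <- sd(loss_to)
  ok <- mean(loss_tl) <= mean(loss_to) + threshold_c * s
  structure(ok, loss_transfer = loss_tl, loss_target_only = loss_to)
}
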