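# Bootstrap internal validation: train on resamples-with-replacement of
# the target cohort, evaluate every resampled model on the original
# target, summarize each metric across runs.

#' Performance report
#'
#' Per-metric mean and standard deviation across bootstrap runs.
#'
#' @param metric_matrix B x 5 matrix of per-run metric values (columns
#'   brier, cal_intercept, cal_slope, auc, auprc).
#' @param n_failed_resamples resamples redrawn for having a single
#'   outcome class.
#' @return object of class `performance_report`: a data frame
#'   (metric, mean, sd) plus counts.
#' @export
performance_report <- function(metric_matrix, n_failed_resamples = 0L) {
  stopifnot(is.matrix(metric_matrix),
            identical(colnames(metric_matrix), metric_names))
  B <- nrow(metric_matrix)
  mean_ <- apply(metric_matrix, 2, mean, na.rm = TRUE)
  sd_ <- if (B == 1) setNames(rep(0, ncol(metric_matrix)), metric_names)
         else apply(metric_matrix, 2, sd, na.rm = TRUE)
  structure(list(metrics = data.frame(metric = metric_names,
                                      mean = unname(mean_),
                                      sd = unname(sd_)),
                 n_bootstrap = B,
                 n_failed_resamples = as.integer(n_failed_resamples),
                 runs = metric_matrix),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report: B = %d (%d redrawn)>\n",
              x$n_bootstrap, x$n_failed_resamples))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-13s %7.4f (sd %.4f)\n", m$metric[i], m$mean[i], m$sd[i]))
  invisible(x)
}

# Accessors over the two supported target containers: a cohort_dataset
# or a plain list(X = matrix, y = vector).
tgt_n <- function(target) {
  if (inherits(target, "cohort_dataset")) nrow(target$data)
  else nrow(target$X)
}
tgt_y <- function(target) {
  if (inherits(target, "cohort_dataset")) target$data$outcome else target$y
}
tgt_take <- function(target, idx) {
  if (inherits(target, "cohort_dataset")) cohort_subset(target, idx)
  else list(X = target$X[idx, , drop = FALSE], y = target$y[idx])
}

#' Bootstrap internal validation
#'
#' For each of B runs: resample the target rows with replacement, rerun
#' the entire fitting procedure on the resample (the supplied
#' `fit_procedure` is responsible for every data-dependent choice —
#' encoding statistics, penalty cross-validation, transfer fit), and
#' score the resampled model's predictions on the original, untouched
#' target. Resamples with fewer than two rows of either class are redrawn
#' (counted; more than 100 consecutive redraws aborts). Per-run seeds are
#' derived deterministically from `(seed, b)`, so a report is
#' reproducible bit for bit.
#'
#' @param fit_procedure function `(source, target_boot, seed)` returning
#'   an object with `$predict(target) -> probabilities` and (optionally)
#'   `$fit`, the fitted model archived for deviation analysis.
#' @param source source data passed through to `fit_procedure` (may be
#'   `NULL` for target-only models).
#' @param target target data: a [cohort_dataset()] (with `outcome`) or a
#'   list with elements `X` and `y`.
#' @param B bootstrap replications (the full protocol uses 1000;
#'   reduced-scale runs use less).
#' @param seed integer master seed.
#' @return a [performance_report()]; attribute `archive` holds the
#'   per-run `$fit` objects.
#' @export
bootstrap_validate <- function(fit_procedure, source, target, B = 1000,
                               seed = 1L) {
  stopifnot(B >= 1)
  n <- tgt_n(target)
  y_test <- check_binary(tgt_y(target))
  runs <- matrix(NA_real_, nrow = B, ncol = length(metric_names),
                 dimnames = list(NULL, metric_names))
  archive <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    consec <- 0L
    repeat {
      idx <- with_seed(child_seed(seed, 1000L + b * 7L + consec), {
        sample.int(n, n, replace = TRUE)
      })
      # need >= 2 distinct rows of each class so grouped stratified
      # folds remain possible downstream
      u <- unique(idx)
      if (sum(y_test[u] == 1) >= 2 && sum(y_test[u] == 0) >= 2) break
      consec <- consec + 1L
      n_failed <- n_failed + 1L
      if (consec >= 100L)
        stop("bootstrap_validate: 100 consecutive single-class resamples",
             call. = FALSE)
    }
    fit <- fit_procedure(source, tgt_take(target, idx), child_seed(seed, b))
    p <- fit$predict(target)
    runs[b, ] <- suppressWarnings(all_metrics(y_test, p))
    archive[[b]] <- fit$fit
  }
  out <- performance_report(runs, n_failed)
  attr(out, "archive") <- archive
  out
}
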