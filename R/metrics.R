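# Performance measures: overall accuracy (Brier score), calibration
# (intercept and slope of a logistic recalibration), and discriminative
# ability (AUC, area under the precision-recall curve).

#' Brier score
#'
#' Mean squared error between predicted probabilities and the binary
#' outcome: `(1/n) * sum((p - y)^2)`. Lower is better.
#'
#' @param y binary 0/1 outcome vector.
#' @param p predicted probabilities in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
brier <- function(y, p) {
  y <- check_binary(y)
  if (length(y) == 0) stop("brier: empty input", call. = FALSE)
  if (length(p) != length(y) || any(p < 0 | p > 1))
    stop("brier: p must match y in length and lie in [0, 1]", call. = FALSE)
  mean((p - y)^2)
}

#' Area under the ROC curve
#'
#' Concordance probability that a randomly drawn positive outscores a
#' randomly drawn negative, ties counted one half (Mann-Whitney / rank
#' formulation; equals the trapezoidal ROC area).
#'
#' @param y binary 0/1 outcome; both classes must be present.
#' @param scores numeric scores (any monotone transform gives the same
#'   value).
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(y, scores) {
  y <- check_binary(y)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("auc: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated average precision: descending-score prefixes
#' contribute `precision * recall-increment`, with tied scores processed
#' as one block. Baseline of a random ranker is the outcome prevalence.
#'
#' @param y binary 0/1 outcome; at least one positive required.
#' @param scores numeric scores.
#' @return scalar in `[0, 1]`.
#' @export
auprc <- function(y, scores) {
  y <- check_binary(y)
  stopifnot(length(scores) == length(y))
  P <- sum(y == 1)
  if (P == 0) stop("auprc: no positive outcomes", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  # block boundaries: last index of each tied-score run
  ends <- which(c(diff(ss) != 0, TRUE))
  tp <- cumsum(ys)[ends]
  np <- ends # rows taken at each block end
  prec <- tp / np
  dtp <- diff(c(0, tp))
  sum(prec * dtp) / P
}

#' Calibration intercept and slope
#'
#' Two logistic recalibrations of predictions `p` against outcome `y` on
#' the logit scale (`p` clipped to `[1e-6, 1 - 1e-6]` first):
#' \itemize{
#'   \item intercept: calibration-in-the-large, the intercept of
#'     `y ~ 1 + offset(logit(p))` (slope fixed at 1); 0 means no
#'     systematic over/under-prediction.
#'   \item slope: the coefficient of `logit(p)` in a free regression
#'     `y ~ a + b * logit(p)`; 1 means predictions spread correctly.
#' }
#' With constant predictions the slope is undefined: it is returned as
#' `NA` with a warning, the intercept is still computed.
#'
#' @param y binary 0/1 outcome.
#' @param p predicted probabilities.
#' @return list with `intercept` and `slope`.
#' @export
calibration <- function(y, p) {
  y <- check_binary(y)
  stopifnot(length(p) == length(y))
  eps <- 1e-6
  lp <- qlogis(pmin(pmax(p, eps), 1 - eps))
  # calibration-in-the-large: the MLE of a in y ~ a + offset(lp) solves
  # mean(plogis(a + lp)) = mean(y), a monotone 1-D equation; root
  # finding is robust where IRLS can overflow on extreme offsets
  gap <- function(a) mean(plogis(a + lp)) - mean(y)
  intercept <- if (mean(y) == 0) -Inf else if (mean(y) == 1) Inf else
    stats::uniroot(gap, lower = -40, upper = 40, extendInt = "yes",
                   tol = 1e-10)$root
  if (sd(lp) < 1e-12) {
    warning("calibration: constant predictions, slope undefined")
    slope <- NA_real_
  } else {
    fit1 <- suppressWarnings(glm(y ~ lp, family = binomial()))
    slope <- unname(coef(fit1)[2])
  }
  list(intercept = intercept, slope = slope)
}

metric_names <- c("brier", "cal_intercept", "cal_slope", "auc", "auprc")

# All five measures on one prediction vector.
all_metrics <- function(y, p) {
  cal <- calibration(y, p)
  c(brier = brier(y, p), cal_intercept = cal$intercept,
    cal_slope = cal$slope, auc = auc(y, p), auprc = auprc(y, p))
}
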