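# Deviation analysis: which predictors' coefficients differ between the
# source and target cohorts, and how consistently across bootstrap runs.

#' Stack per-run coefficient deviations
#'
#' Collects the fitted deviation `delta = beta_tl - beta_source` from an
#' archive of transfer fits (e.g. from [bootstrap_validate()]) into a
#' B x p matrix. A deviation is counted as nonzero when `|delta| > 1e-10`
#' (solver noise below that is treated as zero).
#'
#' @param run_archive list of [fit_transfer()] results (or any objects
#'   with a named `$delta`).
#' @return B x p numeric matrix, columns named by predictor.
#' @export
collect_deviations <- function(run_archive) {
  stopifnot(length(run_archive) >= 1)
  deltas <- lapply(run_archive, function(f) {
    d <- if (inherits(f, "transfer_fit")) f$delta else f$delta
    if (is.null(d) || is.null(names(d)))
      stop("collect_deviations: archive entry without a named delta",
           call. = FALSE)
    d
  })
  nm <- names(deltas[[1]])
  for (d in deltas) {
    if (!identical(names(d), nm))
      stop("collect_deviations: inconsistent column names across runs",
           call. = FALSE)
  }
  do.call(rbind, deltas)
}

#' Flag consistently detected, significant deviations
#'
#' Per predictor, computes the detection frequency (fraction of runs with
#' a nonzero fitted deviation) and the percentile confidence interval of
#' the deviation over the runs in which it was detected (nonzero). A
#' predictor is flagged when its detection frequency reaches
#' `detection_threshold` (default: at least half the runs) AND the
#' percentile interval at `ci_level` excludes zero. Computing the
#' interval over detected runs keeps the two conditions independent:
#' under L1 selection the all-runs interval of any predictor detected in
#' fewer than 97.5% of runs touches zero exactly, which would make the
#' detection-frequency condition redundant.
#'
#' @param sample_matrix B x p deviation matrix from
#'   [collect_deviations()].
#' @param detection_threshold minimum detection frequency (default 0.5).
#' @param ci_level confidence level of the percentile interval
#'   (default 0.95).
#' @param stratum optional label stored in the report metadata.
#' @return object of class `deviation_report`: a data frame (predictor,
#'   detection_frequency, delta_mean, ci_lower, ci_upper, flagged) sorted
#'   by `|delta_mean|` descending, with metadata attributes.
#' @export
flag_deviations <- function(sample_matrix, detection_threshold = 0.5,
                            ci_level = 0.95, stratum = NA_character_) {
  if (!is.matrix(sample_matrix) || nrow(sample_matrix) == 0 ||
      ncol(sample_matrix) == 0)
    stop("flag_deviations: empty deviation matrix", call. = FALSE)
  B <- nrow(sample_matrix)
  if (B < 20)
    warning(sprintf("flag_deviations: only %d runs; percentile intervals unstable", B))
  alpha <- (1 - ci_level) / 2
  freq <- colMeans(abs(sample_matrix) > 1e-10)
  dmean <- colMeans(sample_matrix)
  ci <- apply(sample_matrix, 2, function(v) {
    nz <- v[abs(v) > 1e-10]
    if (!length(nz)) return(c(0, 0))
    quantile(nz, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  })
  flagged <- freq >= detection_threshold & (ci[1, ] > 0 | ci[2, ] < 0)
  rep <- data.frame(predictor = colnames(sample_matrix),
                    detection_frequency = unname(freq),
                    delta_mean = unname(dmean),
                    ci_lower = unname(ci[1, ]),
                    ci_upper = unname(ci[2, ]),
                    flagged = unname(flagged),
                    stringsAsFactors = FALSE)
  rep <- rep[order(abs(rep$delta_mean), decreasing = TRUE), ]
  rownames(rep) <- NULL
  structure(rep, class = c("deviation_report", "data.frame"),
            B = B, ci_level = ci_level,
            detection_threshold = detection_threshold, stratum = stratum)
}

#' Horizontal-bar plot of flagged deviations
#'
#' One bar per flagged predictor (mean deviation across runs, percentile
#' interval as error bars), ordered by magnitude — the per-stratum layout
#' used to display which predictor-outcome associations differ between
#' the source and target cohorts.
#'
#' @param report a [flag_deviations()] report.
#' @param all_predictors plot every predictor instead of flagged only.
#' @return a ggplot object.
#' @export
plot_deviations <- function(report, all_predictors = FALSE) {
  df <- as.data.frame(report)
  if (!all_predictors) df <- df[df$flagged, , drop = FALSE]
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no flagged deviations") +
             ggplot2::theme_void())
  }
  df$predictor <- factor(df$predictor,
                         levels = rev(df$predictor))
  ggplot2::ggplot(df, ggplot2::aes(x = delta_mean,
                                   y = predictor)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_lower,
                                         xmax = ci_upper),
                            height = 0.25) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "coefficient deviation (target - source)",
                  y = NULL,
                  title = attr(report, "stratum")) +
    ggplot2::theme_minimal()
}
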