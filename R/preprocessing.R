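# Preprocessing: model-matrix encoding with train-only statistics,
# missing-value imputation split by response mode, and dichotomization
# of the source probability.

#' Encoding specification
#'
#' Describes how raw cohort columns become the numeric model matrix:
#' which ordered bands the categorical age/education columns use, the
#' reference level dropped from each (k-1 dummy coding), and whether the
#' remaining numeric columns are standardized with training-set statistics.
#'
#' @param age_bands,education_bands ordered category labels.
#' @param dummy_reference named list: reference level per categorical
#'   column (defaults: youngest age band, lowest education band).
#' @param standardize center/scale numeric columns using statistics
#'   learned from the training data only.
#' @return object of class `encoding_spec`.
#' @export
encoding_spec <- function(age_bands = AGE_BANDS,
                          education_bands = EDUC_BANDS,
                          dummy_reference = list(age_band = age_bands[1],
                                                 educ_band = education_bands[1]),
                          standardize = FALSE) {
  stopifnot(length(dummy_reference$age_band) == 1,
            length(dummy_reference$educ_band) == 1)
  structure(list(age_bands = age_bands, education_bands = education_bands,
                 dummy_reference = dummy_reference,
                 standardize = isTRUE(standardize)),
            class = "encoding_spec")
}

default_encoding_spec <- function(cfg = NULL) encoding_spec()

# Encode a raw predictor frame. Dummy columns first (age, education,
# reference level dropped), then the numeric columns in frame order;
# the column order is deterministic so source and target coefficient
# vectors align by name.
encode_frame <- function(raw, spec, fitted_stats = NULL, columns = NULL) {
  if (is.null(columns)) {
    columns <- setdiff(names(raw), c("row_id", "stratum", "mode", "outcome",
                                     "source_probability"))
  }
  raw <- raw[, columns, drop = FALSE]
  mats <- list()
  for (cl in columns) {
    v <- raw[[cl]]
    if (is.factor(v) || is.character(v)) {
      lev <- if (cl == "age_band") spec$age_bands
             else if (cl == "educ_band") spec$education_bands
             else sort(unique(as.character(v)))
      ref <- spec$dummy_reference[[cl]]
      if (is.null(ref)) ref <- lev[1]
      vv <- as.character(v)
      unseen <- setdiff(unique(vv[!is.na(vv)]), lev)
      if (length(unseen))
        stop(sprintf("encode: unseen level(s) in column '%s': %s", cl,
                     paste(unseen, collapse = ", ")), call. = FALSE)
      keep <- setdiff(lev, ref)
      m <- sapply(keep, function(l) as.numeric(vv == l))
      if (!is.matrix(m)) m <- matrix(m, nrow = nrow(raw))
      colnames(m) <- paste0(cl, "_", gsub("[^0-9A-Za-z]+", "_", keep))
      mats[[cl]] <- m
    } else {
      m <- matrix(as.numeric(v), ncol = 1)
      colnames(m) <- cl
      mats[[cl]] <- m
    }
  }
  X <- do.call(cbind, mats)
  rownames(X) <- NULL
  stats <- fitted_stats
  if (is.null(stats)) {
    stats <- list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)),
                  columns = colnames(X), standardized = spec$standardize)
    names(stats$center) <- names(stats$scale) <- colnames(X)
    if (spec$standardize) {
      stats$center <- colMeans(X, na.rm = TRUE)
      sc <- apply(X, 2, sd, na.rm = TRUE)
      sc[!is.finite(sc) | sc < 1e-12] <- 1  # constant column: pass through centered
      stats$scale <- sc
    }
  } else {
    if (!identical(stats$columns, colnames(X)))
      stop("encode: model-matrix columns differ from fitted statistics",
           call. = FALSE)
  }
  if (stats$standardized) {
    X <- sweep(X, 2, stats$center, "-")
    X <- sweep(X, 2, stats$scale, "/")
  }
  list(X = X, stats = stats)
}

#' Encode a cohort into a numeric model matrix
#'
#' Dummy-codes the categorical band columns (reference level dropped) and
#' passes numeric predictors through, optionally standardizing them with
#' statistics learned from a training set. Column order is deterministic
#' and identical across cohorts sharing a predictor set, so coefficient
#' vectors are alignable by name. When `fitted_stats` is supplied (e.g.
#' encoding a test set), only those training statistics are used — no
#' statistic is recomputed from the new data.
#'
#' @param data a [cohort_dataset()] (or plain data frame).
#' @param spec an [encoding_spec()].
#' @param fitted_stats statistics returned by a previous `encode()` call
#'   on the training data; `NULL` to learn them from `data`.
#' @param mode `"self"` or `"proxy"`: selects the predictor set; `NULL`
#'   encodes all predictor columns of a plain data frame.
#' @return list with the numeric matrix `X` and the (learned or passed
#'   through) `stats`.
#' @export
encode <- function(data, spec = encoding_spec(), fitted_stats = NULL,
                   mode = NULL) {
  if (inherits(data, "cohort_dataset")) {
    cols <- if (identical(mode, "proxy")) data$proxy_predictor_cols
            else data$predictor_cols
    encode_frame(data$data, spec, fitted_stats, columns = cols)
  } else {
    encode_frame(data, spec, fitted_stats)
  }
}

#' Dichotomize the source dementia probability
#'
#' Maps the continuous algorithmic probability to a binary pseudo-outcome:
#' label 1 iff `prob >= threshold`. The default threshold is 0.5;
#' alternatives such as 0.25 and 0.75 are accepted.
#'
#' @param prob numeric vector in `[0, 1]`.
#' @param threshold cut point in `(0, 1)`.
#' @return integer 0/1 vector.
#' @export
dichotomize_source <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1))
    stop("prob must lie in [0, 1]", call. = FALSE)
  as.integer(prob >= threshold)
}

# Declared range of a column, if known (for clipping imputed values).
column_range <- function(name) {
  if (name %in% names(COLUMN_RANGES)) return(COLUMN_RANGES[[name]])
  if (grepl("^score[0-9]+$", name)) return(c(0, 10))
  NULL
}

#' Impute missing predictor values, split by response mode
#'
#' Runs independently within the self-respondent and proxy-respondent
#' subsets, on each subset's own predictor set, so the two response modes
#' never inform each other. Two strategies:
#' \describe{
#'   \item{`iterative_forest`}{chained random-forest regressions /
#'     classifications over the incomplete columns, initialized with
#'     mean/mode fills and iterated until the change in imputed values
#'     stops decreasing (at most 10 sweeps), in the spirit of missForest.}
#'   \item{`mean_mode`}{column mean for numeric, mode for categorical.}
#' }
#' Bounded columns are rounded/clipped back to their declared ranges.
#' Complete data pass through unchanged.
#'
#' @param data a [cohort_dataset()].
#' @param strategy `"iterative_forest"` or `"mean_mode"`.
#' @param seed integer seed for the forest fits.
#' @return the cohort with no missing cells in its predictor columns.
#' @export
impute <- function(data, strategy = c("iterative_forest", "mean_mode"),
                   seed = 1L) {
  strategy <- match.arg(strategy)
  df <- data$data
  for (md in c("self", "proxy")) {
    rows <- which(df$mode == md)
    if (!length(rows)) next
    cols <- if (md == "self") data$predictor_cols else data$proxy_predictor_cols
    cols <- intersect(cols, names(df))
    sub <- df[rows, cols, drop = FALSE]
    all_na <- vapply(sub, function(v) all(is.na(v)), logical(1))
    if (any(all_na))
      stop(sprintf("impute: column(s) entirely missing within %s subset: %s",
                   md, paste(cols[all_na], collapse = ", ")), call. = FALSE)
    if (!anyNA(sub)) next
    sub <- switch(strategy,
                  mean_mode = impute_mean_mode(sub),
                  iterative_forest = impute_forest(sub, child_seed(seed,
                                                   if (md == "self") 11L else 12L)))
    df[rows, cols] <- sub
  }
  data$data <- df
  data
}

impute_mean_mode <- function(sub) {
  for (cl in names(sub)) {
    v <- sub[[cl]]
    na <- is.na(v)
    if (!any(na)) next
    if (is.factor(v) || is.character(v)) {
      tab <- table(v[!na])
      fill <- names(tab)[which.max(tab)]
      v[na] <- fill
    } else {
      fill <- mean(v[!na])
      rng <- column_range(cl)
      if (!is.null(rng)) fill <- pmin(pmax(round(fill), rng[1]), rng[2])
      v[na] <- fill
    }
    sub[[cl]] <- v
  }
  sub
}

impute_forest <- function(sub, seed, max_sweeps = 10, num_trees = 100) {
  na_map <- lapply(sub, is.na)
  incomplete <- names(sub)[vapply(na_map, any, logical(1))]
  # visit columns in order of increasing missingness
  incomplete <- incomplete[order(vapply(na_map[incomplete], sum, numeric(1)))]
  cur <- impute_mean_mode(sub)
  prev_change <- Inf
  best <- cur
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    for (cl in incomplete) {
      na <- na_map[[cl]]
      train <- cur[!na, , drop = FALSE]
      test <- cur[na, , drop = FALSE]
      y <- train[[cl]]
      train_x <- train[, setdiff(names(cur), cl), drop = FALSE]
      test_x <- test[, setdiff(names(cur), cl), drop = FALSE]
      is_cat <- is.factor(y) || is.character(y)
      fit <- ranger::ranger(
        x = train_x, y = if (is_cat) factor(y) else y,
        num.trees = num_trees, seed = child_seed(seed, sweep * 131L + match(cl, incomplete)),
        classification = is_cat, respect.unordered.factors = "order",
        num.threads = 1, verbose = FALSE)
      pred <- predict(fit, data = test_x, num.threads = 1)$predictions
      if (is_cat) {
        pred <- as.character(pred)
        if (is.factor(cur[[cl]])) pred <- factor(pred, levels = levels(cur[[cl]]))
      } else {
        rng <- column_range(cl)
        if (!is.null(rng)) pred <- pmin(pmax(round(pred), rng[1]), rng[2])
      }
      cur[[cl]][na] <- pred
    }
    # missForest-style stopping: change in imputed values between sweeps
    num <- 0; den <- 0; mis <- 0; nmis <- 0
    for (cl in incomplete) {
      na <- na_map[[cl]]
      if (is.numeric(cur[[cl]])) {
        num <- num + sum((cur[[cl]][na] - prev[[cl]][na])^2)
        den <- den + sum(cur[[cl]][na]^2)
      } else {
        mis <- mis + sum(as.character(cur[[cl]][na]) != as.character(prev[[cl]][na]))
        nmis <- nmis + sum(na)
      }
    }
    change <- (if (den > 0) num / den else 0) +
      (if (nmis > 0) mis / nmis else 0)
    if (change >= prev_change) return(best)  # keep previous sweep's values
    best <- cur
    prev_change <- change
    if (change == 0) break
  }
  best
}
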