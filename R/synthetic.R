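# Synthetic source/target cohort generator.
#
# Emulates the structure the transfer-learning analysis assumes: a large
# source cohort carrying an imprecise algorithmic dementia probability, a
# small target cohort carrying a gold-standard binary dementia label,
# Hurd-style predictors (age and education bands, sex, bounded cognitive
# scores, ADL/IADL counts, change scores, IQCODE for proxy respondents),
# and stratum-specific sparse deviations between the source and target
# coefficient vectors.

STRATA <- c("White", "Black", "Hispanic")

# Declared ranges of bounded predictor columns (used by the generator,
# by range checks, and by imputation clipping).
COLUMN_RANGES <- list(
  date_orientation = c(0, 4),
  immediate_recall = c(0, 10),
  delayed_recall   = c(0, 10),
  serial7          = c(0, 5),
  backward_count   = c(0, 1),
  name_scissors    = c(0, 1),
  name_cactus      = c(0, 1),
  name_president   = c(0, 1),
  adl              = c(0, 5),
  iadl             = c(0, 5),
  iqcode           = c(0, 5),
  female           = c(0, 1)
)

AGE_BANDS  <- c("70-74", "75-79", "80-84", "85-89", ">89")
EDUC_BANDS <- c("<6", "6-8", "9-11", "12", ">12")

# Raw self-respondent item columns (cognitive battery + change scores).
SELF_COG_COLS <- c("date_orientation", "immediate_recall", "delayed_recall",
                   "serial7", "backward_count", "name_scissors", "name_cactus",
                   "name_president", "recall_change", "serial7_change")
PROXY_COLS <- c("iqcode", "iqcode_change")
DEMO_COLS  <- c("age_band", "educ_band", "female")
FUNC_COLS  <- c("adl", "iadl")

# Run code under a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so generation never perturbs user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration of the synthetic cohort generator
#'
#' Collects every knob of the generator: cohort sizes, dimension of the
#' encoded predictor space, sparsity of the true target coefficient vector
#' and of the source-vs-target coefficient deviation, per-stratum deviation
#' magnitudes, the logit-scale noise perturbing the source probability,
#' the target outcome prevalence the intercept is calibrated to, the
#' missingness mechanism, and the proxy-respondent fraction.
#'
#' Defaults mirror the source/target study design the package emulates:
#' source n = 6630 and target n = 2388 with stratum proportions
#' roughly 77/14/9% (White/Black/Hispanic), a small proxy-respondent share,
#' deviation magnitudes ordered Black > Hispanic > White, and a target
#' dementia prevalence near 12%.
#'
#' @param n_source,n_target cohort sizes.
#' @param p_predictors dimension of the encoded predictor space (dummy
#'   columns for age/education bands plus numeric items); at least 21,
#'   the size of the core Hurd-style predictor set.
#' @param sparsity_beta number of nonzero true target coefficients.
#' @param sparsity_delta number of nonzero source-vs-target deviations.
#' @param delta_magnitude_by_stratum named nonnegative vector, one entry
#'   per stratum, giving the absolute size of each nonzero deviation.
#' @param source_noise_sd scale of the logit-scale logistic noise added
#'   to the source linear predictor before the sigmoid (random error of
#'   the algorithmic probability, on top of the systematic deviation).
#'   Logistic noise makes the dichotomized source label follow a logistic
#'   model in the predictors exactly, so the source LASSO estimates
#'   `beta_source / max(source_noise_sd, 1)` — consistent, at scale 1,
#'   for the source coefficients the transfer step assumes.
#' @param target_prevalence_goal expected target outcome prevalence; the
#'   per-stratum intercept is calibrated to it by bisection.
#' @param missing_rate probability in `[0, 1)` that an eligible predictor
#'   cell is masked by [inject_missingness()].
#' @param missing_mechanism `"MCAR"` (uniform) or `"MAR"` (masking
#'   probability increases with age band).
#' @param proxy_fraction fraction of rows answered by a proxy respondent.
#' @param stratum_proportions named probabilities summing to 1.
#' @param seed integer master seed; identical seed + config gives
#'   bit-identical datasets.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_source = 6630, n_target = 2388,
                             p_predictors = 50,
                             sparsity_beta = 10, sparsity_delta = 4,
                             delta_magnitude_by_stratum =
                               c(White = 0.2, Black = 0.8, Hispanic = 0.5),
                             source_noise_sd = 1,
                             target_prevalence_goal = 0.12,
                             missing_rate = 0,
                             missing_mechanism = c("MCAR", "MAR"),
                             proxy_fraction = 0.06,
                             stratum_proportions =
                               c(White = 0.77, Black = 0.14, Hispanic = 0.09),
                             seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(n_source = n_source, n_target = n_target,
              p_predictors = as.integer(p_predictors),
              sparsity_beta = as.integer(sparsity_beta),
              sparsity_delta = as.integer(sparsity_delta),
              delta_magnitude_by_stratum = delta_magnitude_by_stratum,
              source_noise_sd = source_noise_sd,
              target_prevalence_goal = target_prevalence_goal,
              missing_rate = missing_rate,
              missing_mechanism = missing_mechanism,
              proxy_fraction = proxy_fraction,
              stratum_proportions = stratum_proportions,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) abort_config(sprintf("invalid synthetic_config: field '%s' %s",
                                  field, why))
  }
  chk(is.numeric(cfg$n_source) && cfg$n_source >= 1, "n_source",
      "must be a positive count")
  chk(is.numeric(cfg$n_target) && cfg$n_target >= 1, "n_target",
      "must be a positive count")
  chk(cfg$p_predictors >= n_core_encoded_columns(), "p_predictors",
      sprintf("must be >= %d (the core predictor set)",
              n_core_encoded_columns()))
  chk(cfg$sparsity_beta >= 0 && cfg$sparsity_beta <= cfg$p_predictors,
      "sparsity_beta", "must satisfy 0 <= sparsity_beta <= p_predictors")
  chk(cfg$sparsity_delta >= 0 && cfg$sparsity_delta <= cfg$p_predictors,
      "sparsity_delta", "must satisfy 0 <= sparsity_delta <= p_predictors")
  strata <- names(cfg$stratum_proportions)
  chk(length(strata) >= 1 && all(strata %in% STRATA) &&
        abs(sum(cfg$stratum_proportions) - 1) < 1e-8 &&
        all(cfg$stratum_proportions > 0),
      "stratum_proportions",
      "must be named positive probabilities over White/Black/Hispanic summing to 1")
  chk(all(strata %in% names(cfg$delta_magnitude_by_stratum)),
      "delta_magnitude_by_stratum", "must cover every generated stratum")
  chk(all(cfg$delta_magnitude_by_stratum >= 0),
      "delta_magnitude_by_stratum", "must be nonnegative")
  chk(cfg$source_noise_sd >= 0, "source_noise_sd", "must be nonnegative")
  chk(cfg$target_prevalence_goal > 0 && cfg$target_prevalence_goal < 1,
      "target_prevalence_goal", "must lie in (0, 1)")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1, "missing_rate",
      "must lie in [0, 1)")
  chk(cfg$proxy_fraction >= 0 && cfg$proxy_fraction < 1, "proxy_fraction",
      "must lie in [0, 1)")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a single integer")
  invisible(cfg)
}

core_raw_columns <- function() c(DEMO_COLS, FUNC_COLS, SELF_COG_COLS)

n_core_encoded_columns <- function() {
  # 4 age dummies + 4 education dummies + female + 8 cognitive items +
  # adl + iadl + 2 change scores
  (length(AGE_BANDS) - 1) + (length(EDUC_BANDS) - 1) + 1 +
    8 + 2 + 2
}

n_extra_scores <- function(cfg) cfg$p_predictors - n_core_encoded_columns()

extra_score_names <- function(cfg) {
  k <- n_extra_scores(cfg)
  if (k <= 0) character(0) else sprintf("score%02d", seq_len(k))
}

# Stratum-specific success probabilities / rates of the raw items,
# emulating the cognitive-score gradients of the real cohorts.
stratum_item_params <- function(stratum) {
  switch(stratum,
    White = list(educ = c(0.005, 0.035, 0.09, 0.35, 0.52),
                 date = 0.92, imm = 0.50, del = 0.40, ser = 0.74,
                 back = 0.94, sci = 0.99, cac = 0.96, pre = 0.97,
                 adl = 0.35, iadl = 0.30),
    Black = list(educ = c(0.03, 0.09, 0.18, 0.32, 0.38),
                 date = 0.90, imm = 0.44, del = 0.33, ser = 0.46,
                 back = 0.85, sci = 0.98, cac = 0.80, pre = 0.97,
                 adl = 0.50, iadl = 0.45),
    Hispanic = list(educ = c(0.17, 0.25, 0.18, 0.19, 0.21),
                    date = 0.86, imm = 0.42, del = 0.33, ser = 0.50,
                    back = 0.85, sci = 0.97, cac = 0.90, pre = 0.92,
                    adl = 0.60, iadl = 0.60))
}

# Draw the raw predictor frame for one stratum (all items populated;
# proxy blanking happens later). A per-row latent cognitive ability
# shifts every item's success probability, reproducing the within-person
# correlation of real cognitive batteries (and of functional
# limitations, which load negatively).
draw_raw_predictors <- function(n, stratum, cfg) {
  pr <- stratum_item_params(stratum)
  age_probs <- c(0.38, 0.27, 0.19, 0.10, 0.06)
  ability <- rnorm(n)
  pshift <- function(base, load = 0.7) plogis(qlogis(base) + load * ability)
  df <- data.frame(
    age_band = factor(sample(AGE_BANDS, n, TRUE, prob = age_probs),
                      levels = AGE_BANDS),
    educ_band = factor(sample(EDUC_BANDS, n, TRUE, prob = pr$educ),
                       levels = EDUC_BANDS),
    female = rbinom(n, 1, 0.55),
    adl = pmin(stats::rpois(n, pr$adl * exp(-0.4 * ability)), 5),
    iadl = pmin(stats::rpois(n, pr$iadl * exp(-0.4 * ability)), 5),
    date_orientation = rbinom(n, 4, pshift(pr$date)),
    immediate_recall = rbinom(n, 10, pshift(pr$imm)),
    delayed_recall = rbinom(n, 10, pshift(pr$del)),
    serial7 = rbinom(n, 5, pshift(pr$ser)),
    backward_count = rbinom(n, 1, pshift(pr$back)),
    name_scissors = rbinom(n, 1, pshift(pr$sci)),
    name_cactus = rbinom(n, 1, pshift(pr$cac)),
    name_president = rbinom(n, 1, pshift(pr$pre)),
    recall_change = rnorm(n),
    serial7_change = rnorm(n),
    stringsAsFactors = FALSE
  )
  for (nm in extra_score_names(cfg)) {
    df[[nm]] <- rbinom(n, 10, pshift(0.5, load = 0.3))
  }
  df
}

stratum_sizes <- function(n, proportions) {
  sizes <- floor(n * proportions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * proportions - floor(n * proportions)
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1
  }
  sizes
}

#' Generate true per-stratum coefficient vectors and sparse deviations
#'
#' Per stratum: a sparse true target coefficient vector (`sparsity_beta`
#' nonzeros at random positions, each scaled to a comparable standardized
#' effect), a sparse deviation (`sparsity_delta` nonzeros of exactly the
#' configured per-stratum magnitude, random signs), and
#' `beta_source = beta_target + delta`. The target intercept is calibrated
#' by bisection on a large probe sample so the expected outcome prevalence
#' matches `target_prevalence_goal`.
#'
#' @param config a [synthetic_config()].
#' @param probe_n probe-sample size used for coefficient scaling and
#'   intercept calibration.
#' @return an object of class `true_parameters` with per-stratum
#'   `beta_target`, `beta_source`, `delta` (named over encoded columns;
#'   intercept kept separately) and their support sets.
#' @export
generate_true_parameters <- function(config, probe_n = 50000) {
  validate_synthetic_config(config)
  cfg <- config
  strata <- names(cfg$stratum_proportions)
  spec <- default_encoding_spec(cfg)
  with_seed(child_seed(cfg$seed, 1L), {
    out <- list()
    for (s in strata) {
      raw <- draw_raw_predictors(probe_n, s, cfg)
      X <- encode_frame(raw, spec)$X
      p <- ncol(X)
      stopifnot(p == cfg$p_predictors)
      sds <- apply(X, 2, sd)
      sds[sds < 1e-8] <- 1
      beta <- numeric(p)
      names(beta) <- colnames(X)
      supp_b <- sort(sample.int(p, cfg$sparsity_beta))
      beta[supp_b] <- sample(c(-1, 1), cfg$sparsity_beta, TRUE) *
        runif(cfg$sparsity_beta, 0.3, 0.7) / sds[supp_b]
      delta <- numeric(p)
      names(delta) <- colnames(X)
      # deviations live on high-information quantitative items
      # (recall-type 0-10 scores; probe SD >= 1.5), mirroring where
      # cohort deviations are observed; a fixed-size coefficient shift
      # on a band dummy or a low-variance item is not identifiable at
      # the target sizes this design studies
      is_band <- grepl("^(age_band|educ_band)_", colnames(X))
      eligible <- which(!is_band & apply(X, 2, sd) >= 1.5)
      if (length(eligible) < cfg$sparsity_delta) eligible <- seq_len(p)
      supp_d <- sort(sample(eligible, cfg$sparsity_delta))
      mag <- cfg$delta_magnitude_by_stratum[[s]]
      if (cfg$sparsity_delta > 0) {
        delta[supp_d] <- sample(c(-1, 1), cfg$sparsity_delta, TRUE) * mag
      }
      lp <- drop(X %*% beta)
      b0 <- calibrate_intercept(lp, cfg$target_prevalence_goal)
      # source intercept absorbs the mean shift of the deviation so the
      # source marginal prevalence stays comparable to the target's
      # (deviations change associations, not the base rate)
      out[[s]] <- list(
        intercept = b0,
        intercept_source = b0 - sum(delta * colMeans(X)),
        beta_target = beta,
        beta_source = beta + delta,
        delta = delta,
        support_beta = supp_b,
        support_delta = if (cfg$sparsity_delta > 0) supp_d else integer(0)
      )
    }
    structure(list(by_stratum = out, column_names = names(out[[1]]$beta_target),
                   p = cfg$p_predictors),
              class = "true_parameters")
  })
}

# 1-D bisection for the intercept hitting a prevalence goal in
# expectation over the probe linear predictor.
calibrate_intercept <- function(lp, goal) {
  f <- function(b0) mean(plogis(b0 + lp)) - goal
  lo <- -30; hi <- 30
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' Generate a source/target cohort pair
#'
#' Draws mixed-design predictors within their declared ranges, simulates
#' the target outcome as Bernoulli(sigmoid(intercept + X beta_target)),
#' and the source probability as sigmoid(intercept + X beta_source + eps)
#' with logit-scale Gaussian noise eps. A `proxy_fraction` of rows is
#' flagged as proxy respondents: their cognitive-item columns are marked
#' not-applicable (NA) and an informative IQCODE (plus its change score)
#' is generated from the row's true linear predictor instead.
#'
#' @param config a [synthetic_config()].
#' @param params matching [generate_true_parameters()] output.
#' @return list with elements `source` and `target`, each a
#'   [cohort_dataset()].
#' @export
generate_cohorts <- function(config, params) {
  validate_synthetic_config(config)
  if (!inherits(params, "true_parameters") || params$p != config$p_predictors)
    stop("dimension mismatch between config$p_predictors and params",
         call. = FALSE)
  tgt <- with_seed(child_seed(config$seed, 2L),
                   draw_cohort(config, params, "target"))
  src <- with_seed(child_seed(config$seed, 3L),
                   draw_cohort(config, params, "source"))
  list(source = src, target = tgt)
}

draw_cohort <- function(cfg, params, role) {
  n <- if (role == "source") cfg$n_source else cfg$n_target
  strata <- names(cfg$stratum_proportions)
  sizes <- stratum_sizes(n, cfg$stratum_proportions)
  spec <- default_encoding_spec(cfg)
  pieces <- lapply(seq_along(strata), function(k) {
    s <- strata[k]
    ns <- sizes[k]
    if (ns == 0) return(NULL)
    raw <- draw_raw_predictors(ns, s, cfg)
    X <- encode_frame(raw, spec)$X
    pp <- params$by_stratum[[s]]
    lp_t <- pp$intercept + drop(X %*% pp$beta_target)
    lp_s <- pp$intercept_source + drop(X %*% pp$beta_source)
    raw$stratum <- s
    if (role == "target") {
      raw$outcome <- rbinom(ns, 1, plogis(lp_t))
    } else {
      eps <- if (cfg$source_noise_sd > 0) stats::rlogis(ns, 0, cfg$source_noise_sd) else 0
      raw$source_probability <- plogis(lp_s + eps)
    }
    raw$.lp_true <- lp_t
    raw
  })
  df <- do.call(rbind, pieces)
  n <- nrow(df)
  df$mode <- ifelse(runif(n) < cfg$proxy_fraction, "proxy", "self")
  # informative proxy instrument from the true linear predictor
  lp_std <- (df$.lp_true - mean(df$.lp_true)) / max(sd(df$.lp_true), 1e-8)
  df$iqcode <- pmin(pmax(3.3 + 0.5 * lp_std + rnorm(n, 0, 0.35), 0), 5)
  df$iqcode_change <- 0.15 * lp_std + rnorm(n, 0, 0.4)
  df$.lp_true <- NULL
  is_proxy <- df$mode == "proxy"
  for (cl in c(SELF_COG_COLS, extra_score_names(cfg))) df[[cl]][is_proxy] <- NA
  df$iqcode[!is_proxy] <- NA
  df$iqcode_change[!is_proxy] <- NA
  prefix <- if (role == "source") "S" else "T"
  df$row_id <- sprintf("%s%06d", prefix, seq_len(n))
  # shuffle so stratum blocks are not contiguous
  df <- df[sample.int(n), , drop = FALSE]
  rownames(df) <- NULL
  cohort_dataset(df, role = role, config = cfg)
}

#' Construct a cohort dataset
#'
#' Light S3 container: a data frame with per-row `row_id`, `stratum`
#' (White/Black/Hispanic), `mode` (self/proxy), predictor columns, and —
#' depending on the role — a binary `outcome` (target) or a
#' `source_probability` in `[0, 1]` (source).
#'
#' @param data data frame as above.
#' @param role `"source"` or `"target"`.
#' @param config optional originating [synthetic_config()] (records which
#'   extra score columns exist).
#' @param predictor_cols,proxy_predictor_cols raw column-name sets used
#'   for the self-respondent and proxy-respondent model spaces; derived
#'   from the generator layout when omitted.
#' @return object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(data, role = c("target", "source"),
                           config = NULL, predictor_cols = NULL,
                           proxy_predictor_cols = NULL) {
  role <- match.arg(role)
  extras <- if (!is.null(config)) extra_score_names(config) else
    grep("^score[0-9]+$", names(data), value = TRUE)
  if (is.null(predictor_cols))
    predictor_cols <- c(DEMO_COLS, FUNC_COLS, SELF_COG_COLS, extras)
  if (is.null(proxy_predictor_cols))
    proxy_predictor_cols <- c(DEMO_COLS, FUNC_COLS, PROXY_COLS)
  need <- c("row_id", "stratum", "mode",
            if (role == "target") "outcome" else "source_probability")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("cohort_dataset: missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(data = data, role = role,
                 predictor_cols = predictor_cols,
                 proxy_predictor_cols = proxy_predictor_cols),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset: role=%s, n=%d, %d self / %d proxy>\n",
              x$role, nrow(x$data), sum(x$data$mode == "self"),
              sum(x$data$mode == "proxy")))
  invisible(x)
}

# Row subset keeping class and attributes (used by bootstrap and cells).
cohort_subset <- function(cohort, idx) {
  out <- cohort
  out$data <- cohort$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Inject missingness into a cohort's predictor cells
#'
#' Masks eligible predictor cells according to the configured mechanism.
#' Under MCAR every eligible cell is masked independently with probability
#' `missing_rate`; under MAR the masking probability increases with the
#' row's age band (multipliers 0.4/0.7/1.0/1.3/1.6 across the five bands,
#' mean 1, so the overall rate stays near `missing_rate`). Outcome,
#' stratum, mode, row id and the age band itself (the MAR conditioning
#' variable) are never masked; structurally not-applicable cells (e.g.
#' cognitive items of proxy rows) are skipped.
#'
#' @param data a [cohort_dataset()].
#' @param config a [synthetic_config()] (uses `missing_rate`,
#'   `missing_mechanism`, `seed`).
#' @return the cohort with masked cells set to `NA`.
#' @export
inject_missingness <- function(data, config) {
  validate_synthetic_config(config)
  if (config$missing_rate == 0) return(data)
  df <- data$data
  eligible <- setdiff(union(data$predictor_cols, data$proxy_predictor_cols),
                      "age_band")
  eligible <- intersect(eligible, names(df))
  seed_slot <- if (data$role == "source") 4L else 5L
  with_seed(child_seed(config$seed, seed_slot), {
    n <- nrow(df)
    row_mult <- if (config$missing_mechanism == "MAR") {
      c(0.4, 0.7, 1.0, 1.3, 1.6)[as.integer(df$age_band)]
    } else rep(1, n)
    for (cl in eligible) {
      ok <- !is.na(df[[cl]])
      pr <- pmin(config$missing_rate * row_mult, 0.99)
      mask <- ok & (runif(n) < pr)
      df[[cl]][mask] <- NA
    }
  })
  data$data <- df
  data
}

#' Write / read a cohort as delimited text with a JSON schema sidecar
#'
#' The CSV holds the data; `<path>.schema.json` declares each column's
#' role (id/stratum/mode/outcome/probability/predictor), the cohort role,
#' and the self/proxy predictor sets, so a round trip restores the
#' `cohort_dataset` exactly.
#'
#' @param cohort a [cohort_dataset()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$data
  fac <- vapply(df, is.factor, logical(1))
  levels_map <- lapply(df[fac], levels)
  for (cl in names(df)[fac]) df[[cl]] <- as.character(df[[cl]])
  write.csv(df, path, row.names = FALSE, na = "")
  schema <- list(role = cohort$role,
                 predictor_cols = cohort$predictor_cols,
                 proxy_predictor_cols = cohort$proxy_predictor_cols,
                 factor_levels = levels_map)
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @param path CSV path written by [write_cohort()].
#' @export
read_cohort <- function(path) {
  schema <- jsonlite::read_json(paste0(path, ".schema.json"),
                                simplifyVector = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = "", check.names = FALSE)
  for (cl in names(schema$factor_levels)) {
    df[[cl]] <- factor(df[[cl]], levels = schema$factor_levels[[cl]])
  }
  df$row_id <- as.character(df$row_id)
  cohort_dataset(df, role = schema$role,
                 predictor_cols = schema$predictor_cols,
                 proxy_predictor_cols = schema$proxy_predictor_cols)
}
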