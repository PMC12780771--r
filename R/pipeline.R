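# Study orchestration: stratified model development (per-race/ethnicity
# self-respondent models, pooled proxy model), comparators, bootstrap
# validation, deviation analysis, comparison tables.

default_strata_plan <- function(strata = STRATA) {
  cells <- lapply(strata, function(s)
    list(name = paste0(s, "_self"), stratum = s, mode = "self"))
  c(cells, list(list(name = "proxy_pooled", stratum = NULL, mode = "proxy")))
}

#' Study configuration
#'
#' Everything a full study run needs: the synthetic generator config (or
#' paths to cohort CSVs written by [write_cohort()]), the analysis cells,
#' the model set, bootstrap count, source dichotomization threshold, CV
#' folds, seed and output directory.
#'
#' @param synthetic a [synthetic_config()], or a list
#'   `list(source = path, target = path)` of cohort CSVs.
#' @param strata_plan list of cells, each `list(name, stratum, mode)`;
#'   `stratum = NULL` pools strata (used for the proxy cell). Default:
#'   one self-respondent cell per stratum plus a pooled proxy cell.
#' @param models subset of `c("transfer", "target_only", "source_only")`.
#' @param B bootstrap replications per model.
#' @param threshold source-probability dichotomization cut (default 0.5).
#' @param K cross-validation folds.
#' @param check_transfer run the negative-transfer guard; when it fails,
#'   the transfer model falls back to target-only fitting for that cell.
#' @param impute_strategy `"iterative_forest"` or `"mean_mode"`; applied
#'   only when missing cells are present.
#' @param standardize standardize numeric predictors with training
#'   statistics inside every fit.
#' @param seed master seed.
#' @param output_dir directory for the written bundle, or `NULL` to only
#'   return it.
#' @return object of class `study_config`.
#' @export
study_config <- function(synthetic = synthetic_config(),
                         strata_plan = NULL,
                         models = c("transfer", "target_only", "source_only"),
                         B = 50, threshold = 0.5, K = 10,
                         check_transfer = TRUE,
                         impute_strategy = "iterative_forest",
                         standardize = FALSE,
                         seed = 1L, output_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(strata_plan)) {
    strata <- if (inherits(synthetic, "synthetic_config"))
      names(synthetic$stratum_proportions) else STRATA
    strata_plan <- default_strata_plan(strata)
  }
  nms <- vapply(strata_plan, `[[`, "", "name")
  if (anyDuplicated(nms))
    abort_config("study_config: duplicated cell names in strata_plan")
  if (is.list(synthetic) && !inherits(synthetic, "synthetic_config")) {
    for (f in unlist(synthetic))
      if (!file.exists(f))
        abort_config(sprintf("study_config: input file does not exist: %s", f))
  }
  structure(list(synthetic = synthetic, strata_plan = strata_plan,
                 models = models, B = B, threshold = threshold, K = K,
                 check_transfer = check_transfer,
                 impute_strategy = impute_strategy,
                 standardize = standardize,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

# deterministic 31-bit polynomial rolling hash of a serialized object
# (manifest id; stays in exact double-integer range)
config_hash <- function(x) {
  s <- jsonlite::serializeJSON(x)
  bytes <- utf8ToInt(s)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

study_needs_source <- function(config) {
  any(c("transfer", "source_only") %in% config$models) || config$check_transfer
}

load_study_cohorts <- function(config) {
  if (inherits(config$synthetic, "synthetic_config")) {
    params <- generate_true_parameters(config$synthetic)
    cohorts <- generate_cohorts(config$synthetic, params)
    if (config$synthetic$missing_rate > 0) {
      cohorts$source <- inject_missingness(cohorts$source, config$synthetic)
      cohorts$target <- inject_missingness(cohorts$target, config$synthetic)
    }
    c(cohorts, list(params = params))
  } else {
    # lazy I/O: the source file is only read when a model needs it
    src <- if (study_needs_source(config))
      read_cohort(config$synthetic$source) else NULL
    list(source = src,
         target = read_cohort(config$synthetic$target), params = NULL)
  }
}

cell_rows <- function(cohort, cell) {
  df <- cohort$data
  keep <- df$mode == cell$mode
  if (!is.null(cell$stratum)) keep <- keep & df$stratum == cell$stratum
  which(keep)
}

# Model-fitting procedures handed to bootstrap_validate. Each returns
# list(predict = fn(target_cohort_or_list) -> probs, fit = archived fit).
make_procedures <- function(beta_source, spec, mode, cfg) {
  enc <- function(cohort, stats = NULL)
    encode(cohort, spec, fitted_stats = stats, mode = mode)
  list(
    transfer = function(source, tb, seed) {
      etr <- enc(tb)
      tf <- fit_transfer(etr$X, tb$data$outcome, beta_source,
                         K = cfg$K, seed = seed, groups = tb$data$row_id)
      list(predict = function(tg) predict(tf, enc(tg, etr$stats)$X),
           fit = tf)
    },
    target_only = function(source, tb, seed) {
      etr <- enc(tb)
      cv <- cv_select_lambda(etr$X, tb$data$outcome, K = cfg$K, seed = seed,
                             groups = tb$data$row_id)
      fit <- fit_lasso_logistic(etr$X, tb$data$outcome, cv$lambda, tol = 1e-6)
      list(predict = function(tg) predict(fit, enc(tg, etr$stats)$X),
           fit = fit)
    },
    source_only = function(source, tb, seed) {
      list(predict = function(tg) predict(beta_source, enc(tg)$X),
           fit = beta_source)
    }
  )
}

#' Run the full stratified study
#'
#' End to end: generate (or load) the source/target cohorts, impute
#' missing predictor cells per response mode, then for every analysis
#' cell: encode the cell's model matrices, fit the source-knowledge LASSO
#' on the dichotomized source probability, optionally apply the
#' negative-transfer guard, bootstrap-validate every requested model
#' against the original target rows, run the deviation analysis on the
#' transfer model's run archive, and assemble a comparison table. A cell
#' whose stage fails is recorded with its error; other cells continue.
#'
#' @param config a [study_config()].
#' @return object of class `study_result`: per-cell reports, comparison
#'   tables, deviation reports, and a run manifest (seeds, selected
#'   penalties, config hash). Written to `config$output_dir` when set.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dat <- load_study_cohorts(config)
  spec <- encoding_spec(standardize = config$standardize)
  has_na <- function(co, cols) anyNA(co$data[, intersect(cols, names(co$data))])
  cells <- list()
  logs <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logs <<- c(logs, msg)
    message(msg)
  }
  for (role in c("source", "target")) {
    co <- dat[[role]]
    if (is.null(co)) next
    if (has_na(co, union(co$predictor_cols, co$proxy_predictor_cols))) {
      imp_seed <- child_seed(config$seed, 7L)
      say("%s: imputing missing predictors (%s, seed %d)", role,
          config$impute_strategy, imp_seed)
      dat[[role]] <- impute(co, config$impute_strategy, seed = imp_seed)
    }
  }
  for (ci in seq_along(config$strata_plan)) {
    cell <- config$strata_plan[[ci]]
    res <- tryCatch(
      run_cell(cell, dat, spec, config, child_seed(config$seed, 100L + ci), say),
      error = function(e) {
        say("cell %s: FAILED (%s)", cell$name, conditionMessage(e))
        list(error = conditionMessage(e))
      })
    cells[[cell$name]] <- res
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("demtransfer")),
    config_hash = config_hash(config[setdiff(names(config), "output_dir")]),
    seed = config$seed, B = config$B, K = config$K,
    threshold = config$threshold, models = config$models,
    lambda_selected = lapply(cells, function(cl)
      if (is.null(cl$error)) cl$lambda_selected else NULL))
  out <- structure(list(cells = cells, manifest = manifest, log = logs,
                        config = config),
                   class = "study_result")
  if (!is.null(config$output_dir)) write_study_bundle(out, config$output_dir)
  out
}

run_cell <- function(cell, dat, spec, config, seed, say) {
  say("cell %s: start (stratum=%s, mode=%s)", cell$name,
      if (is.null(cell$stratum)) "pooled" else cell$stratum, cell$mode)
  needs_source <- study_needs_source(config)
  src <- if (needs_source)
    cohort_subset(dat$source, cell_rows(dat$source, cell)) else NULL
  tgt <- cohort_subset(dat$target, cell_rows(dat$target, cell))
  if (nrow(tgt$data) < 20 || (needs_source && nrow(src$data) < 20))
    stop(sprintf("cell %s: too few rows (source %d, target %d)", cell$name,
                 if (needs_source) nrow(src$data) else NA_integer_,
                 nrow(tgt$data)))
  beta_source <- NULL
  if (needs_source) {
    esrc <- encode(src, spec, mode = cell$mode)
    y_src <- dichotomize_source(src$data$source_probability, config$threshold)
    beta_source <- fit_source_lasso(esrc$X, y_src, K = config$K,
                                    seed = child_seed(seed, 1L))
    say("cell %s: source lasso fitted (lambda %.4g, %d nonzero)", cell$name,
        beta_source$lambda, sum(abs(beta_source$coefficients) > 1e-10))
  }
  etgt <- encode(tgt, spec, mode = cell$mode)
  guard_triggered <- FALSE
  if (config$check_transfer && "transfer" %in% config$models) {
    ok <- detect_transferability(NULL, NULL, etgt$X, tgt$data$outcome,
                                 K = min(config$K, 5),
                                 seed = child_seed(seed, 2L),
                                 beta_source = beta_source)
    guard_triggered <- !isTRUE(as.logical(ok))
    say("cell %s: transferability check: %s", cell$name,
        if (guard_triggered) "NEGATIVE (transfer falls back to target-only)"
        else "transferable")
  }
  procs <- make_procedures(beta_source, spec, cell$mode, config)
  reports <- list()
  lambda_selected <- list()
  all_models <- c("transfer", "target_only", "source_only")
  for (m in config$models) {
    proc_name <- if (m == "transfer" && guard_triggered) "target_only" else m
    Bm <- if (m == "source_only") 1L else config$B
    # seed keyed by the procedure actually run: a guarded transfer model
    # reproduces the target-only report exactly
    rep <- bootstrap_validate(procs[[proc_name]], src, tgt, B = Bm,
                              seed = child_seed(seed, 10L + match(proc_name, all_models)))
    reports[[m]] <- rep
    if (m == "transfer" && !guard_triggered) {
      ark <- attr(rep, "archive")
      lambda_selected[[m]] <- vapply(ark, function(f) f$lambda_transfer, 0)
    }
    say("cell %s: model %s validated (B=%d)", cell$name, m, Bm)
  }
  deviation <- NULL
  if ("transfer" %in% names(reports) && !guard_triggered) {
    ark <- attr(reports$transfer, "archive")
    deviation <- suppressWarnings(
      flag_deviations(collect_deviations(ark),
                      stratum = if (is.null(cell$stratum)) "pooled"
                                else cell$stratum))
    say("cell %s: deviation analysis (%d flagged)", cell$name,
        sum(deviation$flagged))
  }
  list(cell = cell, reports = reports,
       comparison = compare_models(reports),
       deviation = deviation,
       beta_source = beta_source,
       guard_triggered = guard_triggered,
       lambda_source = if (!is.null(beta_source)) beta_source$lambda else NULL,
       lambda_selected = lambda_selected,
       n_source = if (needs_source) nrow(src$data) else NA_integer_,
       n_target = nrow(tgt$data))
}

#' Model comparison table
#'
#' One row per model; columns are the five performance measures with
#' their bootstrap SDs, plus a `best` marker column per measure: lowest
#' Brier, calibration intercept nearest 0, slope nearest 1, highest
#' AUC/AUPRC. All models tied for best are marked.
#'
#' @param reports named list of [performance_report()] objects computed
#'   on the same test data.
#' @return data frame of class `model_comparison`.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  rows <- lapply(names(reports), function(m) {
    r <- reports[[m]]$metrics
    out <- data.frame(model = m)
    for (i in seq_len(nrow(r))) {
      out[[r$metric[i]]] <- r$mean[i]
      out[[paste0(r$metric[i], "_sd")]] <- r$sd[i]
    }
    out
  })
  tab <- do.call(rbind, rows)
  score <- list(
    brier = function(v) v,                 # lower better
    cal_intercept = function(v) abs(v),    # nearest 0
    cal_slope = function(v) abs(v - 1),    # nearest 1
    auc = function(v) -v,                  # higher better
    auprc = function(v) -v)
  for (m in names(score)) {
    s <- score[[m]](tab[[m]])
    best <- !is.na(s) & abs(s - min(s, na.rm = TRUE)) < 1e-12
    tab[[paste0(m, "_best")]] <- best
  }
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

write_study_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(result$log, file.path(dir, "run.log"))
  for (nm in names(result$cells)) {
    cl <- result$cells[[nm]]
    if (!is.null(cl$error)) {
      writeLines(cl$error, file.path(dir, paste0(nm, ".error.txt")))
      next
    }
    write.csv(as.data.frame(cl$comparison),
              file.path(dir, paste0(nm, ".comparison.csv")),
              row.names = FALSE)
    jsonlite::write_json(as.data.frame(cl$comparison),
                         file.path(dir, paste0(nm, ".comparison.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(cl$deviation))
      write.csv(as.data.frame(cl$deviation),
                file.path(dir, paste0(nm, ".deviations.csv")),
                row.names = FALSE)
    if (!is.null(cl$beta_source))
      jsonlite::write_json(
        list(intercept = cl$beta_source$intercept,
             coefficients = as.list(cl$beta_source$coefficients),
             lambda = cl$beta_source$lambda),
        file.path(dir, paste0(nm, ".beta_source.json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %d cells, seed %d>\n",
              length(x$cells), x$config$seed))
  for (nm in names(x$cells)) {
    cl <- x$cells[[nm]]
    if (!is.null(cl$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", nm, cl$error))
    } else {
      cat(sprintf("  %s (n_source=%d, n_target=%d)%s\n", nm, cl$n_source,
                  cl$n_target,
                  if (cl$guard_triggered) " [negative-transfer guard]" else ""))
      print(cl$comparison, digits = 3)
    }
  }
  invisible(x)
}
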