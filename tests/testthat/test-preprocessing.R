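# Encoding, train-only statistics, imputation split by response mode,
# and source-probability dichotomization.

test_that("categorical bands get k-1 dummies with the reference dropped", {
  st <- tiny_study(2, n_source = 100, n_target = 150)
  enc <- encode(st$target)
  cn <- colnames(enc$X)
  expect_length(grep("^age_band_", cn), 4)
  expect_length(grep("^educ_band_", cn), 4)
  expect_false(any(grepl("70_74|_6$", grep("^age_band_", cn, value = TRUE))))
  expect_equal(ncol(enc$X), st$cfg$p_predictors)
  expect_false(anyNA(enc$X))
})

test_that("encoding a test set reuses training statistics only", {
  st <- tiny_study(4, n_source = 100, n_target = 300)
  spec <- encoding_spec(standardize = TRUE)
  tr <- demtransfer:::cohort_subset(st$target, 1:200)
  te <- demtransfer:::cohort_subset(st$target, 201:300)
  etr <- encode(tr, spec)
  ete <- encode(te, spec, fitted_stats = etr$stats)
  # corrupting the test rows must not change how they are scaled
  te2 <- te
  te2$data$immediate_recall <- pmin(te2$data$immediate_recall + 3, 10)
  ete2 <- encode(te2, spec, fitted_stats = etr$stats)
  shift <- ete2$X[, "immediate_recall"] - ete$X[, "immediate_recall"]
  manual <- (te2$data$immediate_recall - te$data$immediate_recall) /
    etr$stats$scale[["immediate_recall"]]
  expect_equal(shift, manual, tolerance = 1e-12)
  # identical data, refit stats => identical matrices
  expect_equal(encode(tr, spec)$X, etr$X)
})

test_that("standardization falls back to scale 1 on constant columns", {
  df <- data.frame(a = c(1, 1, 1, 1), b = c(0, 1, 2, 3))
  enc <- demtransfer:::encode_frame(df, encoding_spec(standardize = TRUE))
  expect_equal(enc$stats$scale[["a"]], 1)
  expect_equal(enc$X[, "a"], rep(0, 4)) # centered, passed through
})

test_that("unseen category levels raise an explicit error", {
  df <- data.frame(age_band = factor(c("70-74", "75-79"),
                                     levels = c("70-74", "75-79")),
                   x = c(1, 2))
  spec <- encoding_spec(age_bands = c("70-74"))
  expect_error(demtransfer:::encode_frame(df, spec), "75-79")
})

test_that("dichotomization thresholds follow the >= convention", {
  expect_identical(dichotomize_source(c(0.7, 0.5, 0.3), 0.5), c(1L, 1L, 0L))
  expect_identical(dichotomize_source(0.3, 0.25), 1L)
  expect_identical(dichotomize_source(0.74, 0.75), 0L)
  expect_error(dichotomize_source(1.2, 0.5), "\\[0, 1\\]")
  expect_error(dichotomize_source(0.5, 0), "threshold")
})

test_that("imputation is idempotent on complete data and fills mean/mode", {
  st <- tiny_study(6, n_source = 100, n_target = 120)
  expect_identical(impute(st$target, "mean_mode")$data, st$target$data)
  tgt <- st$target
  tgt$data$adl[1:3] <- NA
  out <- impute(tgt, "mean_mode")
  expect_false(anyNA(out$data$adl))
  fill <- round(mean(tgt$data$adl, na.rm = TRUE))
  expect_true(all(out$data$adl[1:3] == fill))
  # hand example: mean of [1, NA, 3] is 2
  toy <- tgt
  toy$data$adl <- c(1, NA, 3, rep(2, nrow(toy$data) - 3))
  expect_equal(impute(toy, "mean_mode")$data$adl[2], 2)
})

test_that("imputation runs separately by response mode", {
  st <- tiny_study(8, n_source = 100, n_target = 400, proxy_fraction = 0.3)
  tgt <- st$target
  self_rows <- which(tgt$data$mode == "self")
  tgt$data$adl[self_rows[1:5]] <- NA
  out <- impute(tgt, "mean_mode")
  self_fill <- round(mean(tgt$data$adl[tgt$data$mode == "self"], na.rm = TRUE))
  expect_true(all(out$data$adl[self_rows[1:5]] == self_fill))
  # proxy rows untouched
  proxy_rows <- tgt$data$mode == "proxy"
  expect_identical(out$data$adl[proxy_rows], tgt$data$adl[proxy_rows])
})

test_that("a column entirely missing within a mode subset is an error", {
  st <- tiny_study(10, n_source = 100, n_target = 100)
  tgt <- st$target
  tgt$data$serial7[tgt$data$mode == "self"] <- NA
  expect_error(impute(tgt, "mean_mode"), "serial7")
})

test_that("forest imputation beats mean/mode on MCAR-masked cells", {
  # the generator plants inter-predictor structure (stratum gradients,
  # shared latent risk), which the chained forests can exploit
  rmse <- function(imp, truth, mask_idx, cols) {
    errs <- unlist(lapply(cols, function(cl) {
      idx <- mask_idx[[cl]]
      imp$data[[cl]][idx] - truth$data[[cl]][idx]
    }))
    sqrt(mean(errs^2))
  }
  wins <- numeric(10)
  for (k in 1:10) {
    cfg <- synthetic_config(n_source = 60, n_target = 350, p_predictors = 21,
                            missing_rate = 0.05, proxy_fraction = 0,
                            stratum_proportions = c(White = 1),
                            delta_magnitude_by_stratum = c(White = 0.2),
                            seed = 500 + k)
    params <- generate_true_parameters(cfg, probe_n = 8000)
    cohorts <- generate_cohorts(cfg, params)
    truth <- cohorts$target
    masked <- inject_missingness(truth, cfg)
    num_cols <- c("date_orientation", "immediate_recall", "delayed_recall",
                  "serial7", "adl", "iadl")
    mask_idx <- lapply(setNames(num_cols, num_cols), function(cl)
      which(is.na(masked$data[[cl]])))
    mm <- impute(masked, "mean_mode")
    rf <- impute(masked, "iterative_forest", seed = k)
    wins[k] <- rmse(mm, truth, mask_idx, num_cols) -
      rmse(rf, truth, mask_idx, num_cols)
  }
  expect_gte(mean(wins), 0)
})
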