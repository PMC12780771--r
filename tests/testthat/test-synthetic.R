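# Synthetic cohort generator: configuration contracts, determinism,
# range safety, prevalence calibration, missingness mechanisms, file IO.

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(sparsity_beta = 99, p_predictors = 30),
               "sparsity_beta")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  expect_error(synthetic_config(target_prevalence_goal = 0), "target_prevalence_goal")
  expect_error(synthetic_config(p_predictors = 5), "p_predictors")
  expect_error(
    synthetic_config(stratum_proportions = c(White = 0.5, Black = 0.5),
                     delta_magnitude_by_stratum = c(White = 0.1)),
    "delta_magnitude_by_stratum")
  expect_error(synthetic_config(source_noise_sd = -1), "source_noise_sd")
})

test_that("identical seed and config give bit-identical parameters and cohorts", {
  a <- tiny_study(3, n_source = 150, n_target = 100)
  b <- tiny_study(3, n_source = 150, n_target = 100)
  expect_identical(a$params, b$params)
  expect_identical(a$source$data, b$source$data)
  expect_identical(a$target$data, b$target$data)
})

test_that("zero deviation sparsity forces beta_source == beta_target", {
  cfg <- synthetic_config(n_source = 100, n_target = 100, p_predictors = 21,
                          sparsity_delta = 0, seed = 5)
  params <- generate_true_parameters(cfg, probe_n = 5000)
  for (s in names(params$by_stratum)) {
    expect_identical(params$by_stratum[[s]]$beta_source,
                     params$by_stratum[[s]]$beta_target)
    expect_true(all(params$by_stratum[[s]]$delta == 0))
  }
})

test_that("deviation magnitudes follow the configured stratum ordering", {
  cfg <- synthetic_config(n_source = 100, n_target = 100, p_predictors = 25,
                          sparsity_delta = 4,
                          delta_magnitude_by_stratum =
                            c(Black = 0.8, Hispanic = 0.5, White = 0.2),
                          seed = 11)
  params <- generate_true_parameters(cfg, probe_n = 5000)
  mx <- vapply(params$by_stratum, function(s) max(abs(s$delta)), 0)
  expect_gt(mx[["Black"]], mx[["Hispanic"]])
  expect_gt(mx[["Hispanic"]], mx[["White"]])
  nz <- vapply(params$by_stratum, function(s) sum(s$delta != 0), 0L)
  expect_true(all(nz == 4L))
})

test_that("bounded predictors respect their declared ranges on every seed", {
  for (seed in c(1, 17, 301)) {
    st <- tiny_study(seed, n_source = 300, n_target = 200, p = 24,
                     proxy_fraction = 0.1)
    for (co in list(st$source, st$target)) {
      df <- co$data
      for (cl in names(df)) {
        rng <- demtransfer:::column_range(cl)
        if (is.null(rng) || !is.numeric(df[[cl]])) next
        v <- df[[cl]][!is.na(df[[cl]])]
        expect_true(all(v >= rng[1] & v <= rng[2]),
                    label = sprintf("range of %s (seed %d)", cl, seed))
      }
      expect_true(all(df$iqcode[df$mode == "proxy"] >= 0 &
                        df$iqcode[df$mode == "proxy"] <= 5))
      # cognitive items are not-applicable for proxy rows, IQCODE for self
      expect_true(all(is.na(df$immediate_recall[df$mode == "proxy"])))
      expect_true(all(is.na(df$iqcode[df$mode == "self"])))
    }
  }
})

test_that("target prevalence converges to the configured goal", {
  cfg <- synthetic_config(n_source = 100, n_target = 100000,
                          p_predictors = 30, target_prevalence_goal = 0.12,
                          proxy_fraction = 0, seed = 23)
  params <- generate_true_parameters(cfg)
  cohorts <- generate_cohorts(cfg, params)
  expect_lt(abs(mean(cohorts$target$data$outcome) - 0.12), 0.01)
})

test_that("noise-free zero-deviation source probability equals the target sigmoid", {
  cfg <- synthetic_config(n_source = 500, n_target = 100, p_predictors = 21,
                          sparsity_delta = 0, source_noise_sd = 0,
                          proxy_fraction = 0,
                          stratum_proportions = c(White = 1), seed = 9)
  params <- generate_true_parameters(cfg, probe_n = 10000)
  cohorts <- generate_cohorts(cfg, params)
  src <- cohorts$source
  X <- encode(src)$X
  pp <- params$by_stratum$White
  expected <- plogis(pp$intercept + drop(X %*% pp$beta_target))
  expect_equal(src$data$source_probability, expected, tolerance = 1e-12)
})

test_that("MCAR masking hits the configured rate and never touches outcome or stratum", {
  cfg <- synthetic_config(n_source = 4000, n_target = 4000, p_predictors = 30,
                          missing_rate = 0.05, proxy_fraction = 0, seed = 31)
  params <- generate_true_parameters(cfg, probe_n = 10000)
  cohorts <- generate_cohorts(cfg, params)
  tgt <- inject_missingness(cohorts$target, cfg)
  eligible <- setdiff(tgt$predictor_cols, "age_band")
  cells <- unlist(lapply(eligible, function(cl) is.na(tgt$data[[cl]])))
  expect_lt(abs(mean(cells) - 0.05), 0.005)
  expect_false(anyNA(tgt$data$outcome))
  expect_false(anyNA(tgt$data$stratum))
  expect_false(anyNA(tgt$data$age_band))
  # rate zero leaves the dataset untouched
  cfg0 <- synthetic_config(missing_rate = 0, seed = 31)
  expect_identical(inject_missingness(cohorts$target, cfg0)$data,
                   cohorts$target$data)
})

test_that("MAR masking increases with age band", {
  cfg <- synthetic_config(n_source = 100, n_target = 20000, p_predictors = 21,
                          missing_rate = 0.08, missing_mechanism = "MAR",
                          proxy_fraction = 0, seed = 37)
  params <- generate_true_parameters(cfg, probe_n = 10000)
  cohorts <- generate_cohorts(cfg, params)
  tgt <- inject_missingness(cohorts$target, cfg)
  rate_by_band <- vapply(levels(tgt$data$age_band), function(b) {
    rows <- tgt$data$age_band == b
    mean(is.na(tgt$data$immediate_recall[rows]) |
           is.na(tgt$data$delayed_recall[rows]) |
           is.na(tgt$data$adl[rows]))
  }, 0)
  expect_true(all(diff(rate_by_band) > 0))
})

test_that("cohort CSV + schema sidecar round trip restores the object", {
  st <- tiny_study(41, n_source = 120, n_target = 80, proxy_fraction = 0.15,
                   missing_rate = 0.03)
  tgt <- inject_missingness(st$target, st$cfg)
  path <- file.path(withr::local_tempdir(), "target.csv")
  write_cohort(tgt, path)
  back <- read_cohort(path)
  expect_equal(back$data, tgt$data)
  expect_identical(back$role, "target")
  expect_identical(back$predictor_cols, tgt$predictor_cols)
})
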