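test_that("generator is bitwise deterministic and validates its config", {
  cfg <- synthetic_config(n_samples = 60, n_features = 12, seed = 11)
  a <- generate_confounded_dataset(cfg)
  b <- generate_confounded_dataset(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$confounds, b$confounds)
  expect_identical(a$target, b$target)

  expect_error(synthetic_config(n_samples = 0), "positive")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(fractions = c(0.5, 0.5, 0.5, 0)), "summing|sum")
  expect_error(synthetic_config(class_balance = 1), "class_balance")
})

test_that("feature roles partition exactly per fractions (largest remainder)", {
  for (p in c(7, 10, 160)) {
    cfg <- synthetic_config(n_samples = 20, n_features = p,
                            fractions = c(signal = 1/3, confound = 1/3,
                                          mixed = 1/6, null = 1/6), seed = 1)
    ds <- generate_confounded_dataset(cfg)
    counts <- table(factor(ds$feature_roles,
                           c("signal", "confound", "mixed", "null")))
    expect_equal(sum(counts), p)
    # every count within 1 of the exact proportion
    expect_true(all(abs(counts - p * c(1/3, 1/3, 1/6, 1/6)) < 1))
  }
})

test_that("confound 1 carries the requested between-class shift", {
  # Monte-Carlo power oracle: with a standardized shift of 1.5 at n = 300
  # a two-sample t-test on confound 1 rejects at p < 0.001 essentially always.
  rej <- vapply(1:40, function(s) {
    ds <- generate_confounded_dataset(
      synthetic_config(n_samples = 300, n_features = 2,
                       confound_class_shift = 1.5, seed = s))
    group_difference_test(ds$confounds[, 1], ds$target)$p < 0.001
  }, logical(1))
  expect_gte(mean(rej), 0.95)

  # confound 2 is independent of the target by default
  ps <- vapply(1:40, function(s) {
    ds <- generate_confounded_dataset(
      synthetic_config(n_samples = 300, n_features = 2, seed = s))
    group_difference_test(ds$confounds[, 2], ds$target)$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0) # occasionally small by chance...
  expect_lt(mean(ps < 0.05), 0.25) # ...but near the nominal rate
})

test_that("no-signal generator yields target-independent features", {
  cfg <- synthetic_config(n_samples = 200, n_features = 40,
                          confound_class_shift = 0, direct_effect = 0,
                          confound_effect = 1, seed = 7)
  ds <- generate_confounded_dataset(cfg)
  r <- as.numeric(cor(ds$features, ds$target))
  se <- 1 / sqrt(nrow(ds$features))
  expect_lt(abs(mean(r)), 3 * se / sqrt(length(r)) + 3 * se * 0.2)
  # and downstream CV decoding sits at chance
  rep_ <- run_pipeline_cv(ds, "NCR-NZ", small_grid_ridge(), fast_cv(seed = 1))
  expect_gt(mean(rep_$results$auc), 0.4)
  expect_lt(mean(rep_$results$auc), 0.6)
})

test_that("identity shift reproduces the base distribution", {
  cfg <- synthetic_config(n_samples = 2000, n_features = 10, seed = 3)
  base <- generate_confounded_dataset(cfg)
  oos <- generate_shifted_oos(cfg, shift_config(), n_oos = 2000)
  for (k in 1:2) {
    se <- sqrt(var(base$confounds[, k]) / 2000 + var(oos$confounds[, k]) / 2000)
    expect_lt(abs(mean(base$confounds[, k]) - mean(oos$confounds[, k])), 3 * se)
  }
})

test_that("shift configuration moves confound means and coefficients", {
  cfg <- synthetic_config(n_samples = 400, n_features = 20, seed = 9)
  oos <- generate_shifted_oos(cfg, shift_config(confound_mean_shift = c(2, 0)),
                              n_oos = 400)
  base <- generate_shifted_oos(cfg, shift_config(), n_oos = 400)
  se <- sqrt(2 / 400) # both draws have unit-ish variance
  expect_lt(abs((mean(oos$confounds[, 1]) - mean(base$confounds[, 1])) - 2),
            4 * se)

  # zeroing the confound->feature coefficients kills feature-confound
  # correlation in the OOS cohort (no direct target path, so no indirect
  # correlation via the class-shifted confound either)
  cfg0 <- synthetic_config(n_samples = 400, n_features = 20,
                           direct_effect = 0, seed = 9)
  oos0 <- generate_shifted_oos(cfg0, shift_config(confound_effect_scale = 0),
                               n_oos = 400)
  conf_cols <- which(oos0$feature_roles %in% c("confound", "mixed"))
  r <- abs(cor(oos0$features[, conf_cols], oos0$confounds[, 1]))
  expect_lt(max(r), 4 / sqrt(400))

  expect_error(shift_config(confound_sd_scale = 0), "positive")
  expect_error(shift_config(feature_scale = -1), "positive")
})

test_that("ROI time-series generator honours its noise structure", {
  # zero noise: all voxels in an ROI identical, perfect concordance
  ts0 <- generate_roi_timeseries(3, 5, 30, shared_signal_sd = 1,
                                 noise_sd = 0, seed = 2)
  expect_equal(ts0$ROI_1[1, ], ts0$ROI_1[5, ])
  expect_equal(reho_kendalls_w(ts0$ROI_1), 1)

  # determinism
  ts1 <- generate_roi_timeseries(4, 6, 40, seed = 5)
  ts2 <- generate_roi_timeseries(4, 6, 40, seed = 5)
  expect_identical(ts1, ts2)

  # zero shared signal: W near its permutation null
  tsn <- generate_roi_timeseries(2, 12, 20, shared_signal_sd = 0,
                                 noise_sd = 1, seed = 8)
  null_band <- quantile(oracle_w_permutation_null(tsn$ROI_1, 2000),
                        c(0.005, 0.995)) # wide guard band: one draw checked
  w <- reho_kendalls_w(tsn$ROI_1)
  expect_gte(w, null_band[[1]])
  expect_lte(w, null_band[[2]])

  expect_error(generate_roi_timeseries(1, 5, 30), ">= 2")
  expect_error(generate_roi_timeseries(3, 5, 30, shared_signal_sd = 0,
                                       noise_sd = 0), "positive")
})

test_that("dataset round-trips through delimited files and sidecar", {
  cfg <- synthetic_config(n_samples = 30, n_features = 8, seed = 21)
  ds <- generate_confounded_dataset(cfg)
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_dataset(ds, prefix)
  back <- read_dataset(prefix)
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_equal(back$target, ds$target)
  expect_equal(back$feature_roles, ds$feature_roles)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$config$seed, 21)
})
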