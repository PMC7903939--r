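test_that("exactly the eight pipelines are constructible", {
  labels <- all_pipelines()
  expect_length(labels, 8)
  for (l in labels) expect_s3_class(parse_pipeline(l), "pipeline_spec")
  expect_error(pipeline_spec("NCR", "ZAC"), "NCR allows")
  expect_error(pipeline_spec("CVCR", "Z"), "allows")
  expect_error(parse_pipeline("CVCR"), "label")
})

test_that("AUC matches brute force over pairs and handles ties", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(44)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    scores <- round(rnorm(n), 1) # rounding forces occasional ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
  # perfect separation and all-tied scores
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(rep(1, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:5) {
    scores <- rnorm(50)
    labels <- rbinom(50, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("threshold metrics match their confusion-table arithmetic", {
  # sens 0.5, spec 1.0 -> balanced accuracy 0.75
  m1 <- compute_metrics(c(1, -1, -1, -1), c(1, 1, 0, 0), threshold = 0)
  expect_equal(m1$balanced_accuracy, 0.75)
  # P = R = 0.5 -> F1 = 0.5
  m2 <- compute_metrics(c(1, 1, -1), c(1, 0, 1), threshold = 0)
  expect_equal(m2$f1, 0.5)
  # perfect predictions: all three metrics 1
  m3 <- compute_metrics(c(-2, -1, 1, 2), c(0, 0, 1, 1), threshold = 0)
  expect_equal(unlist(m3), c(auc = 1, f1 = 1, balanced_accuracy = 1))
})

test_that("weight aggregation z-scores within run, abs, averages across runs", {
  # two-point z-score symmetry: (1,-1) -> |(0.7071, -0.7071)|
  a <- aggregate_feature_weights(list(c(1, -1)))
  expect_equal(unname(a), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  # identical runs collapse to the single-run value
  w <- rnorm(5)
  expect_equal(aggregate_feature_weights(list(w, w, w)),
               aggregate_feature_weights(list(w)))
  # global sign flips are invisible after abs
  expect_equal(aggregate_feature_weights(list(w, -w)),
               aggregate_feature_weights(list(w)))
  expect_error(aggregate_feature_weights(list(1:3, 1:4)), "length")
})

test_that("top-feature selection is a stable argsort prefix", {
  a <- c(0.3, 0.9, 0.9, 0.1)
  expect_equal(select_top_features(a, 4), c(2, 3, 1, 4))
  expect_equal(select_top_features(a, 1), 2)
  # exact tie at the boundary: lower index wins
  expect_equal(select_top_features(a, 2), c(2, 3))
  expect_equal(select_top_features(c(1, 1, 1), 2), c(1, 2))
  expect_error(select_top_features(a, 0), "k must")
  expect_error(select_top_features(a, 5), "k must")
})

test_that("CV report has one row per repeat x fold and is deterministic", {
  ds <- generate_confounded_dataset(
    synthetic_config(n_samples = 60, n_features = 10, seed = 2))
  cv <- cv_scheme(5, 2, seed = 7)
  rep1 <- run_pipeline_cv(ds, "CVCR-ZAC", small_grid_ridge(), cv)
  expect_equal(nrow(rep1$results), 10)
  expect_true(all(rep1$results$auc >= 0 & rep1$results$auc <= 1))
  rep2 <- run_pipeline_cv(ds, "CVCR-ZAC", small_grid_ridge(), cv)
  expect_identical(rep1$results, rep2$results)
  expect_length(rep1$feature_weights, 10)
  expect_true(all(rep1$feature_weights >= 0))
})

test_that("CVCR fold statistics never touch validation rows", {
  ds <- generate_confounded_dataset(
    synthetic_config(n_samples = 50, n_features = 8, seed = 5))
  tr_idx <- 1:40
  tf_full <- fit_pipeline_transform(ds$features[tr_idx, ],
                                    ds$confounds[tr_idx, ],
                                    pipeline_spec("CVCR", "ZAC"))
  # deleting (or altering) validation rows leaves the fitted statistics
  # bitwise unchanged: they are functions of the training rows only
  ds2 <- ds
  ds2$features[41:50, ] <- 999
  tf_mut <- fit_pipeline_transform(ds2$features[tr_idx, ],
                                   ds2$confounds[tr_idx, ],
                                   pipeline_spec("CVCR", "ZAC"))
  expect_identical(tf_full$confound_model$coefficients,
                   tf_mut$confound_model$coefficients)
  expect_identical(tf_full$z_post$mean, tf_mut$z_post$mean)
})

test_that("WDCR and CVCR coincide in the all-rows fitting limit", {
  ds <- generate_confounded_dataset(
    synthetic_config(n_samples = 40, n_features = 6, seed = 8))
  for (nz in c("NZ", "ZAC", "ZBC")) {
    a <- fit_pipeline_transform(ds$features, ds$confounds,
                                pipeline_spec("WDCR", nz))
    b <- fit_pipeline_transform(ds$features, ds$confounds,
                                pipeline_spec("CVCR", nz))
    expect_lt(max(abs(apply_pipeline_transform(a, ds$features, ds$confounds) -
                      apply_pipeline_transform(b, ds$features, ds$confounds))),
              1e-10)
  }
})

test_that("confound-only signal is decodable raw and gone after removal", {
  # simulation oracle at reduced scale (the acceptance suite runs the full
  # study conditions): signal flows only through confound 1
  ds <- generate_confounded_dataset(pure_confound_config(3, n = 200, p = 50))
  ncr <- run_pipeline_cv(ds, "NCR-NZ", small_grid_ridge(), fast_cv(seed = 1, repeats = 1))
  cvcr <- run_pipeline_cv(ds, "CVCR-ZAC", small_grid_ridge(), fast_cv(seed = 1, repeats = 1))
  expect_gt(mean(ncr$results$auc), 0.75)
  expect_gt(mean(ncr$results$auc) - mean(cvcr$results$auc), 0.15)
  expect_lt(mean(cvcr$results$auc), 0.65)
})

test_that("single-class training folds are reported with their location", {
  ds <- generate_confounded_dataset(
    synthetic_config(n_samples = 20, n_features = 4, seed = 1))
  ds$target <- c(1L, rep(0L, 19)) # one positive: most folds lack it
  expect_error(run_pipeline_cv(ds, "NCR-NZ", small_grid_ridge(),
                               cv_scheme(10, 1, seed = 1)),
               "repeat|fold|class")
})

test_that("evaluation reports write TSV + JSON with provenance", {
  ds <- generate_confounded_dataset(
    synthetic_config(n_samples = 40, n_features = 6, seed = 12))
  rep_ <- run_pipeline_cv(ds, "NCR-Z", small_grid_ridge(), fast_cv(seed = 2, repeats = 1))
  prefix <- file.path(withr::local_tempdir(), "rep")
  paths <- write_evaluation_report(rep_, prefix)
  tab <- read.delim(paths[["folds"]])
  expect_equal(nrow(tab), 5)
  js <- jsonlite::read_json(paths[["summary"]], simplifyVector = TRUE)
  expect_equal(js$pipeline, "NCR-Z")
  expect_true(nzchar(js$results_hash))
})
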