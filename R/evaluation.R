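# Pipeline definitions and the repeated stratified k-fold evaluation engine.
#
# Eight pipelines: NCR-NZ, NCR-Z, and {WDCR, CVCR} x {NZ, ZAC, ZBC}. The
# schemes differ in WHERE the confound-removal (and, for the WDCR arm, the
# z-scoring) statistics are fitted: WDCR fits on the whole dataset before any
# split — data leakage is its defining property — while CVCR fits all
# statistics on each training fold only and applies them to both portions.

PIPELINES <- c("NCR-NZ", "NCR-Z", "WDCR-NZ", "WDCR-ZAC", "WDCR-ZBC",
               "CVCR-NZ", "CVCR-ZAC", "CVCR-ZBC")

#' Specify one of the eight confound-removal x normalization pipelines
#'
#' @param removal `"NCR"` (none), `"WDCR"` (whole-data) or `"CVCR"`
#'   (cross-validated).
#' @param normalization `"NZ"` (none), `"Z"` (NCR only), `"ZAC"` (z-score
#'   after removal) or `"ZBC"` (before); only the eight valid combinations
#'   are constructible.
#' @return an object of class `pipeline_spec`.
#' @export
#' @examples
#' pipeline_spec("CVCR", "ZAC")
#' parse_pipeline("WDCR-ZBC")
pipeline_spec <- function(removal = c("NCR", "WDCR", "CVCR"),
                          normalization = c("NZ", "Z", "ZAC", "ZBC")) {
  removal <- match.arg(removal)
  normalization <- match.arg(normalization)
  valid <- if (removal == "NCR") c("NZ", "Z") else c("NZ", "ZAC", "ZBC")
  if (!normalization %in% valid) {
    stop2(removal, " allows normalization ", paste(valid, collapse = "/"),
          ", not ", normalization)
  }
  structure(list(removal = removal, normalization = normalization,
                 label = paste0(removal, "-", normalization)),
            class = "pipeline_spec")
}

#' @rdname pipeline_spec
#' @param label a string such as `"CVCR-ZAC"`.
#' @export
parse_pipeline <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop2("pipeline label must look like 'CVCR-ZAC'")
  pipeline_spec(parts[1], parts[2])
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat("<pipeline_spec>", x$label, "\n")
  invisible(x)
}

#' All eight valid pipeline labels
#' @return character vector of length 8.
#' @export
all_pipelines <- function() PIPELINES

#' Specify the outer cross-validation scheme
#'
#' @param n_folds outer folds (default 10).
#' @param n_repeats repeats with reshuffled folds (default 10).
#' @param stratified stratify folds by class (default TRUE).
#' @param seed integer seed; each repeat's permutation depends only on
#'   `(seed, repeat index)`.
#' @return an object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_folds = 10, n_repeats = 10, stratified = TRUE,
                      seed = 0) {
  if (n_folds < 2 || n_repeats < 1) stop2("need n_folds >= 2, n_repeats >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Fit a pipeline's transform statistics on a fitting set
#'
#' Fits, in the pipeline's order, the z-score parameters and/or confound
#' model on the supplied rows only. For ZBC the confound model is fitted on
#' z-scored features; for ZAC the z-score is fitted on the residuals. Used
#' with the training fold (CVCR), the whole dataset (WDCR) or the full
#' training sample (deployment).
#'
#' @param features fitting-set feature matrix.
#' @param confounds fitting-set confound matrix.
#' @param pipeline a [pipeline_spec()].
#' @return an object of class `pipeline_transform` holding the fitted pieces.
#' @export
fit_pipeline_transform <- function(features, confounds, pipeline) {
  stopifnot(inherits(pipeline, "pipeline_spec"))
  z_pre <- NULL
  z_post <- NULL
  cm <- NULL
  X <- as_matrix_named(features, "features")
  if (pipeline$normalization %in% c("Z", "ZBC")) {
    z_pre <- fit_zscore(X)
    X <- apply_zscore(X, z_pre)
  }
  if (pipeline$removal != "NCR") {
    cm <- fit_confound_model(X, confounds)
    X <- remove_confounds(X, confounds, cm)
  }
  if (pipeline$normalization == "ZAC") {
    z_post <- fit_zscore(X)
  }
  structure(list(pipeline = pipeline, z_pre = z_pre, confound_model = cm,
                 z_post = z_post),
            class = "pipeline_transform")
}

#' Apply fitted pipeline transform statistics to (new) rows
#'
#' @param transform a [fit_pipeline_transform()] result.
#' @param features feature matrix to transform.
#' @param confounds aligned confound matrix.
#' @return transformed feature matrix.
#' @export
apply_pipeline_transform <- function(transform, features, confounds) {
  stopifnot(inherits(transform, "pipeline_transform"))
  X <- as_matrix_named(features, "features")
  if (!is.null(transform$z_pre)) X <- apply_zscore(X, transform$z_pre)
  if (!is.null(transform$confound_model)) {
    X <- remove_confounds(X, confounds, transform$confound_model)
  }
  if (!is.null(transform$z_post)) X <- apply_zscore(X, transform$z_post)
  X
}

#' Area under the ROC curve (Mann–Whitney form)
#'
#' Probability that a randomly chosen positive sample outscores a randomly
#' chosen negative one, with ties counted one half; computed from average
#' ranks.
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
auc_score <- function(scores, labels) {
  labels <- check_binary_target(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop2("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC, F1 and balanced accuracy from continuous scores
#'
#' Hard labels are `score >= threshold`; balanced accuracy is the mean of
#' sensitivity and specificity; F1 is the harmonic mean of precision and
#' recall for the positive class (0 when precision + recall is 0).
#'
#' @param scores numeric score vector.
#' @param labels binary 0/1 labels; both classes required.
#' @param threshold decision threshold on the score (default 0, the midpoint
#'   of the ±1 target encoding).
#' @return named list: `auc`, `f1`, `balanced_accuracy`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0) {
  labels <- check_binary_target(labels)
  if (length(unique(labels)) < 2) stop2("both classes required")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  list(auc = auc_score(scores, labels), f1 = f1,
       balanced_accuracy = (sens + spec) / 2)
}

#' Aggregate decoder weights across CV runs
#'
#' Within each run the weight vector is z-scored across features (sample SD),
#' absolute values are taken, and the result is averaged elementwise across
#' runs — the standard recipe for ranking predictive features from repeated
#' CV fits.
#'
#' @param per_run_weights list of equal-length numeric weight vectors.
#' @return nonnegative numeric vector of aggregated importance per feature.
#' @export
aggregate_feature_weights <- function(per_run_weights) {
  if (length(per_run_weights) < 1) stop2("need at least one run")
  p <- length(per_run_weights[[1]])
  if (!all(vapply(per_run_weights, length, 1L) == p)) {
    stop2("weight vectors differ in length")
  }
  zs <- vapply(per_run_weights, function(w) {
    s <- stats::sd(w)
    if (s == 0) rep(0, p) else abs((w - mean(w)) / s)
  }, numeric(p))
  out <- rowMeans(matrix(zs, nrow = p))
  names(out) <- names(per_run_weights[[1]])
  out
}

#' Indices of the k features with the largest aggregated weight
#'
#' Ties at the boundary are broken by ascending index (stable).
#'
#' @param aggregate numeric vector from [aggregate_feature_weights()].
#' @param k number of features to select, `1 <= k <= length(aggregate)`.
#' @return integer index vector of length `k`.
#' @export
select_top_features <- function(aggregate, k) {
  p <- length(aggregate)
  if (k < 1 || k > p) stop2("k must lie in [1, ", p, "]")
  order(-aggregate, seq_len(p))[seq_len(k)]
}

#' Run one pipeline under repeated stratified k-fold cross-validation
#'
#' For WDCR pipelines the z-scoring (if ZBC; and the z-scoring of residuals
#' if ZAC) and the confound regression are fitted once on ALL rows before
#' splitting — the whole-data arm stays wholly pre-CV. For CVCR (and the
#' z-score of NCR-Z) every statistic is fitted on the training fold only and
#' applied to both portions. The decoder's hyperparameter is tuned by inner
#' CV on the transformed training fold; metrics come from validation scores.
#'
#' @param dataset a [confound_dataset()].
#' @param pipeline a [pipeline_spec()] or label string.
#' @param estimator an [estimator_spec()].
#' @param cv a [cv_scheme()].
#' @return an `evaluation_report`: `results` data frame (one row per
#'   repeat x fold with AUC, F1, balanced accuracy and the chosen
#'   hyperparameter), `summary` of means/SDs, `feature_weights` aggregated
#'   per [aggregate_feature_weights()], and full provenance.
#' @export
run_pipeline_cv <- function(dataset, pipeline, estimator = estimator_spec("ridge"),
                            cv = cv_scheme()) {
  stopifnot(inherits(dataset, "confound_dataset"),
            inherits(estimator, "estimator_spec"), inherits(cv, "cv_scheme"))
  if (is.character(pipeline)) pipeline <- parse_pipeline(pipeline)
  y <- dataset$target
  n <- length(y)

  whole <- NULL
  X_all <- dataset$features
  if (pipeline$removal == "WDCR") {
    whole <- fit_pipeline_transform(dataset$features, dataset$confounds, pipeline)
    X_all <- apply_pipeline_transform(whole, dataset$features, dataset$confounds)
  }

  rows <- vector("list", cv$n_folds * cv$n_repeats)
  weights <- vector("list", cv$n_folds * cv$n_repeats)
  i <- 0L
  for (r in seq_len(cv$n_repeats)) {
    folds <- stratified_folds(y, cv$n_folds, derive_seed(cv$seed, r),
                              cv$stratified)
    for (f in seq_len(cv$n_folds)) {
      i <- i + 1L
      tr <- folds != f
      if (length(unique(y[tr])) < 2) {
        stop2("single-class training fold at repeat ", r, ", fold ", f)
      }
      if (pipeline$removal == "WDCR") {
        Xtr <- X_all[tr, , drop = FALSE]
        Xva <- X_all[!tr, , drop = FALSE]
      } else {
        tf <- fit_pipeline_transform(dataset$features[tr, , drop = FALSE],
                                     dataset$confounds[tr, , drop = FALSE],
                                     pipeline)
        Xtr <- apply_pipeline_transform(tf, dataset$features[tr, , drop = FALSE],
                                        dataset$confounds[tr, , drop = FALSE])
        Xva <- apply_pipeline_transform(tf, dataset$features[!tr, , drop = FALSE],
                                        dataset$confounds[!tr, , drop = FALSE])
      }
      tuned <- tune_hyperparameter(Xtr, y[tr], estimator,
                                   seed = derive_seed(cv$seed, r, f))
      dec <- fit_decoder(Xtr, y[tr], estimator, tuned$value)
      m <- compute_metrics(predict_scores(dec, Xva), y[!tr])
      rows[[i]] <- data.frame(repeat_idx = r, fold_idx = f, auc = m$auc,
                              f1 = m$f1, balanced_accuracy = m$balanced_accuracy,
                              hyperparameter = tuned$value)
      weights[[i]] <- dec$weights
    }
  }
  results <- do.call(rbind, rows)
  metric_cols <- c("auc", "f1", "balanced_accuracy")
  structure(
    list(results = results,
         summary = data.frame(
           metric = metric_cols,
           mean = vapply(results[metric_cols], mean, 1),
           sd = vapply(results[metric_cols], stats::sd, 1),
           row.names = NULL),
         feature_weights = aggregate_feature_weights(weights),
         pipeline = pipeline, estimator = estimator, cv = cv,
         n_samples = n, n_features = ncol(dataset$features)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %s decoder, %dx%d-fold CV on n = %d, p = %d\n",
              x$pipeline$label, x$estimator$kind, x$cv$n_repeats, x$cv$n_folds,
              x$n_samples, x$n_features))
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.3f (SD %.3f)\n", s$metric[k], s$mean[k], s$sd[k]))
  }
  invisible(x)
}

#' Write an evaluation report as TSV + JSON summary
#'
#' The TSV holds one row per repeat x fold; the JSON summary embeds the
#' aggregate metrics, aggregated feature weights and the full resolved
#' provenance (pipeline, estimator, CV scheme, a content hash of the
#' results).
#'
#' @param report an `evaluation_report`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_evaluation_report <- function(report, prefix) {
  f_tsv <- paste0(prefix, "_folds.tsv")
  f_json <- paste0(prefix, "_summary.json")
  utils::write.table(report$results, f_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(pipeline = report$pipeline$label, estimator = report$estimator$kind,
         cv = unclass(report$cv), n_samples = report$n_samples,
         n_features = report$n_features, summary = report$summary,
         feature_weights = report$feature_weights,
         results_hash = content_hash(report$results)),
    f_json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(folds = f_tsv, summary = f_json))
}
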