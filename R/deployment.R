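# Deployment: finalize one trained pipeline into a single deployable bundle
# and score out-of-sample (OOS) data under four confound-handling methods:
#   1. train-to-test  — apply the train-fitted removal model to OOS (standard)
#   2. test WDCR      — refit removal on the whole OOS sample
#   3. test CVCR      — refit removal per OOS fold, residuals retained
#   4. combined WDCR  — refit removal on train + OOS together, re-split

#' Finalize a trained pipeline into a deployable model
#'
#' Fits the normalization and confound-regression statistics on the FULL
#' training set in the pipeline's order, tunes the decoder hyperparameter by
#' inner CV on the transformed training data, and fits the decoder. Note:
#' for a CVCR pipeline the deployable confound model is fitted on the full
#' training set — numerically identical to WDCR-on-train. A single
#' deployable transform must exist; the WDCR/CVCR distinction lives in the
#' ESTIMATION of generalization performance (the cross-validation scheme),
#' not in the deployed artifact.
#'
#' @param train a [confound_dataset()].
#' @param pipeline a [pipeline_spec()] or label.
#' @param estimator an [estimator_spec()].
#' @param seed integer seed for the inner tuning CV.
#' @return an object of class `deployed_model`: `transform`
#'   (a `pipeline_transform`), `decoder`, `pipeline`, and provenance
#'   (`seed`, `hyperparameter`, `n_train`, names).
#' @export
finalize_model <- function(train, pipeline, estimator = estimator_spec("ridge"),
                           seed = 0) {
  stopifnot(inherits(train, "confound_dataset"))
  if (is.character(pipeline)) pipeline <- parse_pipeline(pipeline)
  tf <- fit_pipeline_transform(train$features, train$confounds, pipeline)
  Xtr <- apply_pipeline_transform(tf, train$features, train$confounds)
  tuned <- tune_hyperparameter(Xtr, train$target, estimator, seed = seed)
  decoder <- fit_decoder(Xtr, train$target, estimator, tuned$value)
  structure(
    list(transform = tf, decoder = decoder, pipeline = pipeline,
         estimator = estimator,
         provenance = list(seed = seed, hyperparameter = tuned$value,
                           n_train = nrow(train$features),
                           feature_names = colnames(train$features),
                           confound_names = colnames(train$confounds))),
    class = "deployed_model"
  )
}

#' @export
print.deployed_model <- function(x, ...) {
  cat(sprintf("<deployed_model> %s + %s (hyperparameter %s), trained on n = %d\n",
              x$pipeline$label, x$decoder$kind,
              format(x$provenance$hyperparameter), x$provenance$n_train))
  invisible(x)
}

check_oos_names <- function(model, oos) {
  if (!identical(colnames(oos$features), model$provenance$feature_names)) {
    stop2("OOS feature names do not match the deployed model")
  }
  if (!identical(colnames(oos$confounds), model$provenance$confound_names)) {
    stop2("OOS confound names do not match the deployed model")
  }
}

# Residuals entering the diagnostics: the feature representation right after
# the confound-removal step (before any post-hoc z-scoring).
residuals_before_zpost <- function(transform, features, confounds) {
  X <- features
  if (!is.null(transform$z_pre)) X <- apply_zscore(X, transform$z_pre)
  if (!is.null(transform$confound_model)) {
    X <- remove_confounds(X, confounds, transform$confound_model)
  }
  X
}

#' Method 1 — apply train-fitted confound removal to OOS data
#'
#' The standard deployment route: the confound-removal (and normalization)
#' statistics fitted on the training sample are applied unchanged to the OOS
#' rows, the train decoder scores the result, and the OOS residuals are
#' audited for residual confounding (they are generically not orthogonal to
#' the OOS confounds, since the removal model was fitted elsewhere).
#'
#' @param model a [finalize_model()] bundle.
#' @param oos a [confound_dataset()] with matching names.
#' @return list: `metrics` (auc/f1/balanced_accuracy), `scores`,
#'   `diagnostics` (a [residual_diagnostics()] report on the OOS residuals;
#'   NULL for NCR pipelines).
#' @export
oos_train_to_test <- function(model, oos) {
  stopifnot(inherits(model, "deployed_model"), inherits(oos, "confound_dataset"))
  check_oos_names(model, oos)
  X <- apply_pipeline_transform(model$transform, oos$features, oos$confounds)
  scores <- predict_scores(model$decoder, X)
  diag_ <- NULL
  if (!is.null(model$transform$confound_model)) {
    res <- residuals_before_zpost(model$transform, oos$features, oos$confounds)
    diag_ <- residual_diagnostics(res, oos$confounds, "oos")
  }
  list(metrics = compute_metrics(scores, oos$target), scores = scores,
       diagnostics = diag_)
}

#' Methods 2 and 3 — self confound removal on the OOS sample
#'
#' The confound regression is re-fitted on the OOS data alone: on the whole
#' OOS sample (`scheme = "WDCR"`), or per OOS fold with the fold residuals
#' retained (`scheme = "CVCR"`; each fold's removal model is fitted on the
#' remaining folds). Train-fitted z-score parameters are then applied in the
#' pipeline's order and the train decoder scores the result. Requires an OOS
#' sample large enough to refit on (`n > c + 1`; at least 2 folds for CVCR).
#'
#' @param model a [finalize_model()] bundle (pipeline must remove confounds).
#' @param oos a [confound_dataset()].
#' @param scheme `"WDCR"` or `"CVCR"`.
#' @param n_folds folds for the CVCR scheme (default 10, capped at `n_oos`;
#'   `n_folds = n_oos` is the leave-one-out limit).
#' @param seed fold-assignment seed for CVCR.
#' @return list: `metrics`, `scores`, `residuals`, `diagnostics`.
#' @export
oos_self_removal <- function(model, oos, scheme = c("WDCR", "CVCR"),
                             n_folds = 10, seed = 0) {
  stopifnot(inherits(model, "deployed_model"), inherits(oos, "confound_dataset"))
  scheme <- match.arg(scheme)
  check_oos_names(model, oos)
  if (model$pipeline$removal == "NCR") {
    stop2("self removal needs a confound-removing pipeline")
  }
  X <- oos$features
  if (!is.null(model$transform$z_pre)) {
    X <- apply_zscore(X, model$transform$z_pre) # ZBC: train z first
  }
  if (scheme == "WDCR") {
    cm <- fit_confound_model(X, oos$confounds)
    res <- remove_confounds(X, oos$confounds, cm)
  } else {
    n <- nrow(X)
    k <- min(as.integer(n_folds), n)
    if (k < 2) stop2("CVCR needs at least 2 folds")
    folds <- stratified_folds(oos$target, k, derive_seed(seed, 29L))
    res <- X * NA_real_
    for (f in seq_len(k)) {
      tr <- folds != f
      cm_f <- fit_confound_model(X[tr, , drop = FALSE],
                                 oos$confounds[tr, , drop = FALSE])
      res[!tr, ] <- remove_confounds(X[!tr, , drop = FALSE],
                                     oos$confounds[!tr, , drop = FALSE], cm_f)
    }
  }
  Xout <- res
  if (!is.null(model$transform$z_post)) {
    Xout <- apply_zscore(Xout, model$transform$z_post) # ZAC: train z params
  }
  scores <- predict_scores(model$decoder, Xout)
  list(metrics = compute_metrics(scores, oos$target), scores = scores,
       residuals = res,
       diagnostics = residual_diagnostics(res, oos$confounds, "oos"))
}

#' Method 4 — whole-data confound removal on train and OOS combined
#'
#' The confound regression (and, for ZBC, the z-scoring) is fitted on the
#' CONCATENATION of the training and OOS rows and applied to all of them;
#' the data are then re-split into their ORIGINAL train/OOS membership (no
#' reshuffling), the decoder is re-fitted — hyperparameter re-tuned — on the
#' train part, and the OOS part is scored. The combined residuals are
#' orthogonal to the confounds over the concatenated sample, but under a
#' distribution shift each part separately retains nonzero residual
#' confound correlations; diagnostics are therefore reported per part.
#'
#' @param train,oos [confound_dataset()]s with matching names.
#' @param pipeline a confound-removing [pipeline_spec()] or label.
#' @param estimator an [estimator_spec()].
#' @param seed integer seed for the inner tuning CV.
#' @return list: `metrics` (OOS part), `scores`,
#'   `diagnostics` (list with `train` and `oos` reports), `decoder`.
#' @export
oos_combined_wdcr <- function(train, oos, pipeline = "WDCR-ZAC",
                              estimator = estimator_spec("ridge"), seed = 0) {
  stopifnot(inherits(train, "confound_dataset"), inherits(oos, "confound_dataset"))
  if (is.character(pipeline)) pipeline <- parse_pipeline(pipeline)
  if (pipeline$removal == "NCR") stop2("combined removal needs a removing pipeline")
  if (!identical(colnames(train$features), colnames(oos$features)) ||
      !identical(colnames(train$confounds), colnames(oos$confounds))) {
    stop2("train and OOS names do not match")
  }
  n_tr <- nrow(train$features)
  feats <- rbind(train$features, oos$features)
  confs <- rbind(train$confounds, oos$confounds)
  # combined arm is whole-combined for every statistic, per the WDCR logic
  tf <- fit_pipeline_transform(feats, confs, pipeline)
  Xall <- apply_pipeline_transform(tf, feats, confs)
  res_all <- residuals_before_zpost(tf, feats, confs)
  is_tr <- seq_len(nrow(feats)) <= n_tr
  tuned <- tune_hyperparameter(Xall[is_tr, , drop = FALSE], train$target,
                               estimator, seed = seed)
  dec <- fit_decoder(Xall[is_tr, , drop = FALSE], train$target, estimator,
                     tuned$value)
  scores <- predict_scores(dec, Xall[!is_tr, , drop = FALSE])
  list(
    metrics = compute_metrics(scores, oos$target), scores = scores,
    diagnostics = list(
      train = residual_diagnostics(res_all[is_tr, , drop = FALSE],
                                   train$confounds, "train"),
      oos = residual_diagnostics(res_all[!is_tr, , drop = FALSE],
                                 oos$confounds, "oos"),
      combined = residual_diagnostics(res_all, confs, "train")
    ),
    decoder = dec
  )
}

#' Serialize a deployed model to JSON (lossless round trip)
#'
#' @param model a `deployed_model`.
#' @param path optional file path.
#' @return JSON string (invisibly if written).
#' @export
deployed_model_to_json <- function(model, path = NULL) {
  tf <- model$transform
  obj <- list(
    type = "deployed_model",
    pipeline = model$pipeline$label,
    estimator = list(kind = model$estimator$kind,
                     inner_folds = model$estimator$inner_folds,
                     grid = model$estimator$grid),
    z_pre = if (!is.null(tf$z_pre)) jsonlite::fromJSON(zscore_params_to_json(tf$z_pre)),
    confound_model = if (!is.null(tf$confound_model)) {
      jsonlite::fromJSON(confound_model_to_json(tf$confound_model))
    },
    z_post = if (!is.null(tf$z_post)) jsonlite::fromJSON(zscore_params_to_json(tf$z_post)),
    decoder = jsonlite::fromJSON(decoder_to_json(model$decoder)),
    provenance = model$provenance
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a deployed model from JSON
#'
#' @param json JSON string or file path.
#' @return a `deployed_model`.
#' @export
deployed_model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  rebuild_z <- function(z) {
    if (is.null(z)) return(NULL)
    zscore_params_from_json(jsonlite::toJSON(z, auto_unbox = TRUE, digits = NA))
  }
  pipeline <- parse_pipeline(obj$pipeline)
  tf <- structure(
    list(pipeline = pipeline, z_pre = rebuild_z(obj$z_pre),
         confound_model = if (!is.null(obj$confound_model)) {
           confound_model_from_json(
             jsonlite::toJSON(obj$confound_model, auto_unbox = TRUE, digits = NA))
         },
         z_post = rebuild_z(obj$z_post)),
    class = "pipeline_transform"
  )
  decoder <- decoder_from_json(
    jsonlite::toJSON(obj$decoder, auto_unbox = TRUE, digits = NA))
  est <- estimator_spec(obj$estimator$kind, grid = obj$estimator$grid,
                        inner_folds = obj$estimator$inner_folds)
  structure(
    list(transform = tf, decoder = decoder, pipeline = pipeline,
         estimator = est, provenance = obj$provenance),
    class = "deployed_model"
  )
}
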