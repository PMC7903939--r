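# Per-feature linear confound regression: the core operator of both the
# whole-data (WDCR) and cross-validated (CVCR) removal schemes. A linear
# model with the confounds (plus intercept) as predictors is fitted to each
# feature separately; the residuals become the "confound-removed" features.

#' Fit per-feature linear confound regression models
#'
#' Ordinary least squares of every feature column on `[1 | confounds]`.
#' Confounds are used as supplied (not standardized): residuals are invariant
#' to affine reparameterization of the confounds, so standardization would be
#' cosmetic. A rank-deficient design triggers a warning and the minimum-norm
#' (pseudo-inverse) solution rather than an error.
#'
#' @param features numeric `n x p` matrix.
#' @param confounds numeric `n x c` matrix, `c >= 1`.
#' @return an object of class `confound_model`: `(c+1) x p` coefficient
#'   matrix (row 1 = intercept), names, and `n_fit`.
#' @export
#' @examples
#' m <- fit_confound_model(cbind(f = c(1, 2, 3, 4)), cbind(z = c(0, 0, 1, 1)))
#' m$coefficients # intercept 1.5, slope 2
fit_confound_model <- function(features, confounds) {
  features <- as_matrix_named(features, "features")
  confounds <- as_matrix_named(confounds, "confounds")
  n <- nrow(features)
  c_ <- ncol(confounds)
  if (nrow(confounds) != n) stop2("row counts differ")
  if (n <= c_ + 1) stop2("need n > c + 1 samples to fit ", c_, " confound(s)")
  A <- cbind(`(intercept)` = 1, confounds)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("rank-deficient confound design; using minimum-norm least squares",
            call. = FALSE)
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% features) / sv$d[pos])
  } else {
    coef <- qr.coef(qrA, features)
  }
  dimnames(coef) <- list(c("(intercept)", colnames(confounds)),
                         colnames(features))
  structure(
    list(coefficients = coef, confound_names = colnames(confounds),
         feature_names = colnames(features), n_fit = n),
    class = "confound_model"
  )
}

#' @export
print.confound_model <- function(x, ...) {
  cat(sprintf("<confound_model> %d feature(s) ~ [1 | %s], fitted on n = %d\n",
              length(x$feature_names),
              paste(x$confound_names, collapse = ", "), x$n_fit))
  invisible(x)
}

#' Residualize features against confounds with a fitted model
#'
#' `residuals = features - [1 | confounds] %*% coefficients`. On the model's
#' own fitting data the residuals are exactly orthogonal to each confound and
#' to the intercept; applied to new data they are generically not — that gap
#' is what the deployment experiments measure.
#'
#' @param features numeric `n x p` matrix with the model's feature names.
#' @param confounds numeric `n x c` matrix with the model's confound names.
#' @param model a [fit_confound_model()] result.
#' @return `n x p` residual matrix, same dimnames as `features`.
#' @export
remove_confounds <- function(features, confounds, model) {
  stopifnot(inherits(model, "confound_model"))
  features <- as_matrix_named(features, "features")
  confounds <- as_matrix_named(confounds, "confounds")
  if (!identical(colnames(features), model$feature_names)) {
    stop2("feature names do not match the fitted model")
  }
  if (!identical(colnames(confounds), model$confound_names)) {
    stop2("confound names do not match the fitted model")
  }
  A <- cbind(1, confounds)
  res <- features - A %*% model$coefficients
  dimnames(res) <- dimnames(features)
  res
}

#' Whole-data confound regression (WDCR) on a dataset
#'
#' Fits the confound model on ALL rows and residualizes all rows — the
#' whole-data scheme, applied before any cross-validation split. The leakage
#' of validation information into the removal step is the defining property
#' of this scheme, not an accident; the fitted model is returned for audit.
#'
#' @param dataset a [confound_dataset()].
#' @return list with `dataset` (features replaced by residuals) and `model`
#'   (the fitted [fit_confound_model()]).
#' @export
wdcr_transform <- function(dataset) {
  stopifnot(inherits(dataset, "confound_dataset"))
  model <- fit_confound_model(dataset$features, dataset$confounds)
  res <- remove_confounds(dataset$features, dataset$confounds, model)
  out <- dataset
  out$features <- res
  list(dataset = out, model = model)
}

#' Serialize a confound model to JSON
#'
#' @param model a `confound_model`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
confound_model_to_json <- function(model, path = NULL) {
  obj <- list(type = "confound_model",
              coefficients = model$coefficients,
              confound_names = model$confound_names,
              feature_names = model$feature_names, n_fit = model$n_fit)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a confound model from JSON
#'
#' @param json JSON string or file path produced by
#'   [confound_model_to_json()].
#' @return a `confound_model`.
#' @export
confound_model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  coef <- as.matrix(obj$coefficients)
  dimnames(coef) <- list(c("(intercept)", obj$confound_names),
                         obj$feature_names)
  structure(
    list(coefficients = coef, confound_names = obj$confound_names,
         feature_names = obj$feature_names, n_fit = obj$n_fit),
    class = "confound_model"
  )
}
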