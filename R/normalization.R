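# Z-score normalization as a fit/apply pair, so it can be placed before
# (ZBC) or after (ZAC) confound removal, or omitted (NZ), with the fitting
# sample controlled by the surrounding scheme.

#' Fit per-feature z-score parameters
#'
#' Column means and sample standard deviations (divisor `n - 1`). Zero-SD
#' columns are flagged rather than raising: residual features can be exactly
#' zero (e.g. a feature identical to a confound).
#'
#' @param features numeric `n x p` matrix, `n >= 2`.
#' @return object of class `zscore_params` with `mean`, `sd`, `feature_names`
#'   and a `zero_sd` logical flag per feature.
#' @export
fit_zscore <- function(features) {
  features <- as_matrix_named(features, "features")
  if (nrow(features) < 2) stop2("need n >= 2 to estimate a standard deviation")
  mu <- colMeans(features)
  sd_ <- apply(features, 2, stats::sd)
  structure(
    list(mean = mu, sd = sd_, feature_names = colnames(features),
         zero_sd = sd_ == 0),
    class = "zscore_params"
  )
}

#' Apply z-score parameters to a feature matrix
#'
#' `(x - mean) / sd` per column; columns flagged as zero-SD map to all zeros.
#'
#' @param features numeric `n x p` matrix with matching feature names.
#' @param params a [fit_zscore()] result.
#' @return `n x p` normalized matrix.
#' @export
apply_zscore <- function(features, params) {
  stopifnot(inherits(params, "zscore_params"))
  features <- as_matrix_named(features, "features")
  if (!identical(colnames(features), params$feature_names)) {
    stop2("feature names do not match the fitted z-score parameters")
  }
  sd_safe <- ifelse(params$zero_sd, 1, params$sd)
  out <- sweep(sweep(features, 2, params$mean, "-"), 2, sd_safe, "/")
  if (any(params$zero_sd)) out[, params$zero_sd] <- 0
  dimnames(out) <- dimnames(features)
  out
}

#' Serialize z-score parameters to JSON
#' @param params a `zscore_params`.
#' @param path optional file path.
#' @return JSON string (invisibly if written).
#' @export
zscore_params_to_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(
    list(type = "zscore_params", mean = params$mean, sd = params$sd,
         feature_names = params$feature_names, zero_sd = params$zero_sd),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize z-score parameters from JSON
#' @param json JSON string or file path.
#' @return a `zscore_params`.
#' @export
zscore_params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(
    list(mean = stats::setNames(obj$mean, obj$feature_names),
         sd = stats::setNames(obj$sd, obj$feature_names),
         feature_names = obj$feature_names, zero_sd = obj$zero_sd),
    class = "zscore_params"
  )
}
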