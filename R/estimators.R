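# Ridge and PLS1 decoders. Both are regression models used as continuous
# scorers for binary decoding: the target is encoded -1/+1, the score is
# X w + b, and hard labels (when needed) come from thresholding at 0.

#' Specify a decoder and its tuning grid
#'
#' @param kind `"ridge"` or `"pls"`.
#' @param grid ordered hyperparameter grid. Default: `10^(-3:3)` for ridge
#'   (penalty lambda), `1:min(20, p, n-2)` for PLS (number of latent
#'   components), resolved against the data at tuning time when NULL.
#' @param inner_folds folds of the inner tuning CV (default 5).
#' @return an object of class `estimator_spec`.
#' @export
estimator_spec <- function(kind = c("ridge", "pls"), grid = NULL,
                           inner_folds = 5) {
  kind <- match.arg(kind)
  if (!is.null(grid)) grid <- as.numeric(unlist(grid)) # YAML may hand a list
  if (!is.null(grid)) {
    if (length(grid) == 0) stop2("hyperparameter grid must be non-empty")
    if (kind == "ridge" && any(grid < 0)) stop2("lambda must be >= 0")
    if (kind == "pls" && any(grid < 1)) stop2("n_components must be >= 1")
  }
  structure(list(kind = kind, grid = grid, inner_folds = as.integer(inner_folds)),
            class = "estimator_spec")
}

resolve_grid <- function(spec, n, p) {
  if (!is.null(spec$grid)) {
    g <- spec$grid
    if (spec$kind == "pls") g <- g[g <= min(p, n - 1)]
    if (length(g) == 0) stop2("no grid value feasible for n = ", n, ", p = ", p)
    return(g)
  }
  if (spec$kind == "ridge") 10^(-3:3) else seq_len(max(1, min(20, p, n - 2)))
}

encode_target <- function(y) 2 * check_binary_target(y) - 1

new_decoder <- function(weights, intercept, kind, hyperparameter, names_) {
  structure(
    list(weights = stats::setNames(as.numeric(weights), names_),
         intercept = as.numeric(intercept), kind = kind,
         hyperparameter = hyperparameter),
    class = "linear_decoder"
  )
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf("<linear_decoder> %s, %d weights, hyperparameter = %s\n",
              x$kind, length(x$weights), format(x$hyperparameter)))
  invisible(x)
}

# Ridge solution path over a vector of lambdas via one symmetric
# eigendecomposition; primal (p x p) when p <= n, dual (n x n) otherwise.
# Returns a p x L matrix of weights on CENTERED data.
ridge_weights_path <- function(Xc, yc, lambdas) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  if (p <= n) {
    ei <- eigen(crossprod(Xc), symmetric = TRUE)
    b <- crossprod(ei$vectors, crossprod(Xc, yc))
    W <- vapply(lambdas, function(l) {
      d <- ei$values + l
      if (l == 0) d[d < max(ei$values, 1) * 1e-12] <- Inf # min-norm at lambda 0
      as.numeric(ei$vectors %*% (b / d))
    }, numeric(p))
  } else {
    ei <- eigen(tcrossprod(Xc), symmetric = TRUE)
    b <- crossprod(ei$vectors, yc)
    W <- vapply(lambdas, function(l) {
      d <- ei$values + l
      if (l == 0) d[d < max(ei$values, 1) * 1e-12] <- Inf
      as.numeric(crossprod(Xc, ei$vectors %*% (b / d)))
    }, numeric(p))
  }
  matrix(W, nrow = p)
}

#' Fit a ridge decoder
#'
#' Intercept-unpenalized ridge: features and the ±1-encoded target are
#' centered, `w = (X'X + lambda I)^-1 X'y` (solved through the dual `n x n`
#' system when `p > n`), and the intercept is `mean(y) - mean(x)' w`. At
#' `lambda = 0` the minimum-norm least-squares solution is returned.
#'
#' @param X numeric `n x p` matrix.
#' @param y_encoded length-`n` vector in `{-1, +1}` (0/1 targets are
#'   re-encoded automatically).
#' @param lambda penalty `>= 0`.
#' @return a `linear_decoder`.
#' @export
#' @examples
#' d <- fit_ridge(matrix(1:3, 3), c(-1, 0, 1) + 2, lambda = 1)
fit_ridge <- function(X, y_encoded, lambda) {
  X <- as_matrix_named(X, "features")
  if (lambda < 0) stop2("lambda must be >= 0")
  if (nrow(X) < 2) stop2("need n >= 2")
  y <- if (all(y_encoded %in% c(0, 1))) encode_target(y_encoded) else y_encoded
  xbar <- colMeans(X)
  ybar <- mean(y)
  w <- ridge_weights_path(sweep(X, 2, xbar), y - ybar, lambda)[, 1]
  new_decoder(w, ybar - sum(xbar * w), "ridge", lambda, colnames(X))
}

# PLS1 coefficient path: columns k = 1..K give the regression weights using
# the first k latent components, on CENTERED data. Covariance-deflation form
# (NIPALS-equivalent for a single response).
pls1_path <- function(Xc, yc, K) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  W <- matrix(0, p, K)
  P <- matrix(0, p, K)
  q <- numeric(K)
  Xd <- Xc
  yd <- yc
  used <- 0L
  tol <- 1e-12 * max(1, sqrt(sum(Xc^2)) * sqrt(sum(yc^2)))
  for (k in seq_len(K)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw <= tol) break
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt <= tol) break
    P[, k] <- crossprod(Xd, t_) / tt
    q[k] <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(P[, k])
    yd <- yd - q[k] * t_
    W[, k] <- w
    used <- k
  }
  B <- matrix(0, p, K)
  if (used > 0) {
    for (k in seq_len(used)) {
      Wk <- W[, seq_len(k), drop = FALSE]
      Pk <- P[, seq_len(k), drop = FALSE]
      B[, k] <- Wk %*% solve(crossprod(Pk, Wk), q[seq_len(k)])
    }
    if (used < K) B[, (used + 1):K] <- B[, used] # path flattens once deflated out
  }
  B
}

#' Fit a PLS1 decoder
#'
#' Partial least squares regression with a single response: latent components
#' are extracted to maximize covariance between the (centered) features and
#' the ±1-encoded target, by the standard deflation algorithm, and the
#' component regression is folded into one weight vector plus intercept.
#' With `n_components` equal to the rank of the centered feature matrix the
#' predictions coincide with ordinary least squares. A target with zero
#' covariance to every feature yields the zero weight vector.
#'
#' @param X numeric `n x p` matrix.
#' @param y_encoded length-`n` vector in `{-1, +1}` (0/1 accepted).
#' @param n_components number of latent components,
#'   `1 <= n_components <= min(p, n - 1)`.
#' @return a `linear_decoder`.
#' @export
fit_pls <- function(X, y_encoded, n_components) {
  X <- as_matrix_named(X, "features")
  n <- nrow(X)
  p <- ncol(X)
  if (n_components < 1 || n_components > min(p, n - 1)) {
    stop2("n_components must lie in [1, min(p, n-1)] = [1, ", min(p, n - 1), "]")
  }
  y <- if (all(y_encoded %in% c(0, 1))) encode_target(y_encoded) else y_encoded
  xbar <- colMeans(X)
  ybar <- mean(y)
  B <- pls1_path(sweep(X, 2, xbar), y - ybar, n_components)
  w <- B[, n_components]
  new_decoder(w, ybar - sum(xbar * w), "pls", as.integer(n_components),
              colnames(X))
}

#' Continuous decoder scores
#'
#' @param decoder a `linear_decoder`.
#' @param X numeric `n x p` matrix, `p` matching the decoder.
#' @return length-`n` numeric score vector (`X w + intercept`).
#' @export
predict_scores <- function(decoder, X) {
  stopifnot(inherits(decoder, "linear_decoder"))
  X <- as_matrix_named(X, "features")
  if (ncol(X) != length(decoder$weights)) {
    stop2("feature count mismatch: decoder has ", length(decoder$weights),
          " weights, data has ", ncol(X), " columns")
  }
  as.numeric(X %*% decoder$weights + decoder$intercept)
}

fit_decoder <- function(X, y_encoded, spec, hyperparameter) {
  if (spec$kind == "ridge") fit_ridge(X, y_encoded, hyperparameter)
  else fit_pls(X, y_encoded, hyperparameter)
}

#' Choose a hyperparameter by inner cross-validation
#'
#' Stratified k-fold CV inside the training data; for each grid value the
#' mean validation AUC is computed (using the solution-path shortcuts, so the
#' whole grid costs little more than one fit per fold) and the maximizer is
#' returned. Exact ties go to the stronger regularization: the larger lambda
#' for ridge, the fewer components for PLS.
#'
#' @param X numeric `n x p` training matrix (already pipeline-transformed).
#' @param y binary 0/1 (or ±1) training target; both classes required.
#' @param spec an [estimator_spec()].
#' @param seed integer seed for the inner fold assignment.
#' @return list with `value` (chosen hyperparameter) and `mean_auc` (named
#'   vector of inner-CV AUC per grid value).
#' @export
tune_hyperparameter <- function(X, y, spec, seed = 0) {
  stopifnot(inherits(spec, "estimator_spec"))
  X <- as_matrix_named(X, "features")
  y01 <- if (all(y %in% c(-1, 1))) as.integer(y > 0) else check_binary_target(y)
  if (length(unique(y01)) < 2) stop2("both classes required for tuning")
  grid <- resolve_grid(spec, nrow(X), ncol(X))
  if (length(grid) == 1) {
    return(list(value = grid, mean_auc = stats::setNames(NA_real_, grid)))
  }
  k <- min(spec$inner_folds, min(table(y01)))
  if (k < 2) stop2("too few samples per class for inner CV")
  folds <- stratified_folds(y01, k, derive_seed(seed, 13L))
  ypm <- 2 * y01 - 1
  aucs <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- ypm[tr]
    xbar <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2, xbar)
    yc <- ytr - mean(ytr)
    Xva <- sweep(X[!tr, , drop = FALSE], 2, xbar)
    yva <- y01[!tr]
    if (length(unique(yva)) < 2) next
    B <- if (spec$kind == "ridge") {
      ridge_weights_path(Xc, yc, grid)
    } else {
      pls1_path(Xc, yc, max(grid))[, grid, drop = FALSE]
    }
    S <- Xva %*% B # intercept is constant per column; AUC is rank-invariant
    aucs[f, ] <- apply(S, 2, auc_score, labels = yva)
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  best <- mean_auc >= max(mean_auc) - 1e-12
  value <- if (spec$kind == "ridge") max(grid[best]) else min(grid[best])
  list(value = value, mean_auc = stats::setNames(mean_auc, grid))
}

#' Serialize a linear decoder to JSON
#' @param decoder a `linear_decoder`.
#' @param path optional file path.
#' @return JSON string (invisibly if written).
#' @export
decoder_to_json <- function(decoder, path = NULL) {
  js <- jsonlite::toJSON(
    list(type = "linear_decoder", kind = decoder$kind,
         hyperparameter = decoder$hyperparameter,
         intercept = decoder$intercept, weights = decoder$weights),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a linear decoder from JSON
#' @param json JSON string or file path.
#' @return a `linear_decoder`.
#' @export
decoder_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  new_decoder(unlist(obj$weights), obj$intercept, obj$kind,
              obj$hyperparameter, names(obj$weights))
}
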