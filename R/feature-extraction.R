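# ReHo and FC feature extraction from ROI-grouped time-series.

#' Kendall's coefficient of concordance across voxel time-series
#'
#' Regional homogeneity of one ROI: each voxel's series is ranked over time
#' (average ranks for ties) and
#' `W = 12 S / (K^2 (T^3 - T) - K * C)`, where `S` is the sum of squared
#' deviations of per-timepoint rank sums from their mean and `C` the standard
#' tie-correction term summed over voxels. `W` lies in `[0, 1]`: 1 for
#' perfectly concordant series, 0 when rank sums are all equal.
#'
#' @param voxel_ts numeric `K x T` matrix, `K >= 2` voxels, `T >= 3`
#'   timepoints.
#' @return scalar concordance in `[0, 1]`.
#' @export
#' @examples
#' x <- rbind(1:10, 1:10 + 0.5)
#' reho_kendalls_w(x) # identical rankings: 1
reho_kendalls_w <- function(voxel_ts) {
  voxel_ts <- as.matrix(voxel_ts)
  K <- nrow(voxel_ts)
  T_ <- ncol(voxel_ts)
  if (K < 2) stop2("need at least 2 voxels")
  if (T_ < 3) stop2("need at least 3 timepoints")
  if (anyNA(voxel_ts)) stop2("missing values in time-series")
  const <- apply(voxel_ts, 1, function(r) max(r) == min(r))
  if (all(const)) stop2("all voxel time-series are constant; ranks undefined")
  ranks <- t(apply(voxel_ts, 1, rank))
  rank_sums <- colSums(ranks)
  S <- sum((rank_sums - mean(rank_sums))^2)
  tie_corr <- sum(apply(voxel_ts, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }))
  denom <- K^2 * (T_^3 - T_) - K * tie_corr
  if (denom <= 0) stop2("degenerate ties leave concordance undefined")
  W <- 12 * S / denom
  min(max(W, 0), 1)
}

#' ReHo feature vector: one concordance value per ROI
#'
#' @param roi_ts a [generate_roi_timeseries()] object or named list of
#'   voxel-by-time matrices.
#' @return named numeric vector (one `W` per ROI) with attribute
#'   `space = "ReHo"`.
#' @export
reho_features <- function(roi_ts) {
  vals <- vapply(roi_ts, reho_kendalls_w, numeric(1))
  names(vals) <- names(roi_ts) %||% paste0("ROI_", seq_along(roi_ts))
  structure(vals, space = "ReHo")
}

#' Average voxel time-series within each ROI
#'
#' @param roi_ts named list of `K x T` voxel time-series matrices.
#' @return `R x T` matrix of per-ROI mean series, rownames = ROI labels.
#' @export
roi_average <- function(roi_ts) {
  out <- t(vapply(roi_ts, colMeans, numeric(ncol(roi_ts[[1]]))))
  rownames(out) <- names(roi_ts) %||% paste0("ROI_", seq_along(roi_ts))
  out
}

#' Vectorize the strict lower triangle of a symmetric matrix
#'
#' Row-major over `i > j`: `(2,1), (3,1), (3,2), (4,1), ...`, giving
#' `R(R-1)/2` entries for an `R x R` matrix. This fixed, documented order is
#' what all FC feature names (`FC_i_j`) refer to.
#'
#' @param mat symmetric `R x R` matrix.
#' @return numeric vector of length `R(R-1)/2` with names `FC_i_j`.
#' @export
#' @examples
#' length(vectorize_lower(diag(160))) # 12720
vectorize_lower <- function(mat) {
  R <- nrow(mat)
  if (R < 2 || ncol(mat) != R) stop2("mat must be square with R >= 2")
  ij <- lower_tri_index(R)
  out <- mat[ij]
  names(out) <- paste0("FC_", ij[, 1], "_", ij[, 2])
  out
}

#' Rebuild a symmetric matrix from its lower-triangle vectorization
#'
#' Inverse of [vectorize_lower()] up to the diagonal, which is set to `diag`.
#'
#' @param vec vector of length `R(R-1)/2`.
#' @param diag diagonal value (default 0).
#' @return symmetric `R x R` matrix.
#' @export
unvectorize_lower <- function(vec, diag = 0) {
  R <- (1 + sqrt(1 + 8 * length(vec))) / 2
  if (abs(R - round(R)) > 1e-9) stop2("length is not R(R-1)/2 for integer R")
  R <- as.integer(round(R))
  ij <- lower_tri_index(R)
  mat <- matrix(0, R, R)
  mat[ij] <- vec
  mat[ij[, c(2, 1), drop = FALSE]] <- vec
  diag(mat) <- diag
  mat
}

lower_tri_index <- function(R) {
  i <- unlist(lapply(2:R, function(r) rep(r, r - 1)))
  j <- unlist(lapply(2:R, function(r) seq_len(r - 1)))
  cbind(i, j)
}

#' Functional-connectivity features from ROI-averaged time-series
#'
#' Pearson correlation between every pair of ROI mean series, Fisher
#' z-transformed (`atanh`), strict lower triangle vectorized in the
#' row-major `i > j` order of [vectorize_lower()]. For 160 ROIs this yields
#' the canonical 12,720-dimensional connectivity vector. Correlations of
#' magnitude 1 are clipped to `1 - 1e-15` so the transform stays finite.
#'
#' @param roi_means `R x T` matrix of ROI-averaged series (`R >= 2`,
#'   `T >= 3`), e.g. from [roi_average()].
#' @return named numeric vector of length `R(R-1)/2` with attribute
#'   `space = "FC"`.
#' @export
fc_features <- function(roi_means) {
  roi_means <- as.matrix(roi_means)
  R <- nrow(roi_means)
  if (R < 2) stop2("need at least 2 ROIs")
  if (ncol(roi_means) < 3) stop2("need at least 3 timepoints")
  sds <- apply(roi_means, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- (rownames(roi_means) %||% paste0("ROI_", seq_len(R)))[sds == 0]
    stop2("constant mean time-series in ", paste(bad, collapse = ", "))
  }
  C <- stats::cor(t(roi_means))
  C[C >= 1] <- 1 - 1e-15
  C[C <= -1] <- -(1 - 1e-15)
  Z <- atanh(C)
  structure(vectorize_lower(Z), space = "FC")
}

#' Extract both feature spaces for a collection of subjects
#'
#' @param subjects list of `roi_timeseries` objects (one per subject).
#' @return list with `reho` (subjects x ROIs matrix) and `fc`
#'   (subjects x R(R-1)/2 matrix).
#' @export
extract_feature_tables <- function(subjects) {
  reho <- t(vapply(subjects, function(s) as.numeric(reho_features(s)),
                   numeric(length(subjects[[1]]))))
  colnames(reho) <- names(reho_features(subjects[[1]]))
  fc1 <- fc_features(roi_average(subjects[[1]]))
  fc <- t(vapply(subjects, function(s) as.numeric(fc_features(roi_average(s))),
                 numeric(length(fc1))))
  colnames(fc) <- names(fc1)
  list(reho = reho, fc = fc)
}
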