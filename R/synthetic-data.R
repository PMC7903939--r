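# Synthetic confounded-data generator.
#
# Emulates the structure of a sex-decoding problem from brain features: a
# binary target with (near-)balanced classes, a primary confound ("brain
# size"-like) strongly shifted between the classes, a secondary confound
# ("age"-like) unrelated to the target by default, and features mixing a
# direct target signal with confound-mediated signal. A companion generator
# draws shifted out-of-sample cohorts for deployment experiments.

#' Configuration for the synthetic confounded-data generator
#'
#' Defaults describe the standard study conditions used throughout the
#' package's tests and examples: 300 samples, 160 ReHo-like features, two
#' confounds of which the first has a between-class standardized mean
#' difference of 1.5 (large enough that a two-sample t-test on it rejects at
#' p < 0.001 at this n, the hallmark of a brain-size-style confound), a
#' moderate direct effect, and unit confound effect and noise.
#'
#' @param n_samples number of samples.
#' @param n_features number of features.
#' @param n_confounds number of confounds (>= 1; default 2, "size"-like and
#'   "age"-like).
#' @param class_balance proportion of class 1 in (0, 1); class counts are
#'   fixed (largest-remainder) so both classes are always present.
#' @param confound_class_shift standardized mean difference of confound 1
#'   between the classes (within-class SD is 1).
#' @param secondary_class_shift optional standardized mean difference of
#'   confound 2 between classes (0 = independent of the target, the default).
#' @param direct_effect per-feature coefficient of the (±1-coded) target on
#'   signal-carrying features (>= 0).
#' @param confound_effect per-feature coefficient magnitude of confounds on
#'   confound-carrying features (>= 0); signs vary across features.
#' @param fractions named proportions of `signal` / `confound` / `mixed` /
#'   `null` features; must sum to 1. Counts are derived by largest-remainder
#'   rounding so they sum exactly to `n_features`.
#' @param noise_sd residual noise SD (> 0).
#' @param seed integer seed; identical seed and config give bitwise-identical
#'   output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 300, n_features = 160,
                             n_confounds = 2, class_balance = 0.5,
                             confound_class_shift = 1.5,
                             secondary_class_shift = 0,
                             direct_effect = 0.3, confound_effect = 1,
                             fractions = c(signal = 0.2, confound = 0.3,
                                           mixed = 0.2, null = 0.3),
                             noise_sd = 1, seed = 1) {
  if (n_samples < 2 || n_features < 1 || n_confounds < 1) {
    stop2("counts must be positive (n_samples >= 2, n_features, n_confounds >= 1)")
  }
  if (class_balance <= 0 || class_balance >= 1) {
    stop2("class_balance must lie strictly in (0, 1)")
  }
  if (direct_effect < 0 || confound_effect < 0) stop2("effects must be >= 0")
  if (noise_sd <= 0) stop2("noise_sd must be > 0")
  if (length(fractions) != 4 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-12) {
    stop2("fractions must be 4 nonnegative proportions summing to 1")
  }
  names(fractions) <- c("signal", "confound", "mixed", "null")
  structure(
    list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
         n_confounds = as.integer(n_confounds), class_balance = class_balance,
         confound_class_shift = confound_class_shift,
         secondary_class_shift = secondary_class_shift,
         direct_effect = direct_effect, confound_effect = confound_effect,
         fractions = fractions, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Configuration of a distribution shift for out-of-sample cohorts
#'
#' Describes how an out-of-sample cohort differs from the base generator:
#' confound means and variances, the strength of the confound-to-feature
#' coefficients, an overall feature scale, and the class-confound coupling.
#' The all-zero-shift / unit-scale default leaves the generating distribution
#' identical to the base.
#'
#' @param confound_mean_shift per-confound additive mean shift (recycled).
#' @param confound_sd_scale per-confound positive SD scale (recycled).
#' @param confound_effect_scale multiplier on confound-to-feature coefficients.
#' @param feature_scale positive overall feature scale.
#' @param target_confound_shift additive change to the class shift of
#'   confound 1 (alters how strongly the confound tracks the target).
#' @return an object of class `shift_config`.
#' @export
shift_config <- function(confound_mean_shift = 0, confound_sd_scale = 1,
                         confound_effect_scale = 1, feature_scale = 1,
                         target_confound_shift = 0) {
  if (any(confound_sd_scale <= 0)) stop2("confound_sd_scale must be positive")
  if (feature_scale <= 0) stop2("feature_scale must be positive")
  structure(
    list(confound_mean_shift = confound_mean_shift,
         confound_sd_scale = confound_sd_scale,
         confound_effect_scale = confound_effect_scale,
         feature_scale = feature_scale,
         target_confound_shift = target_confound_shift),
    class = "shift_config"
  )
}

# Structural parameters (feature roles, loading signs) are drawn from a seed
# derived from config$seed only, so a shifted OOS cohort shares the same
# feature architecture as its base sample.
generator_structure <- function(config) {
  p <- config$n_features
  counts <- largest_remainder(config$fractions, p)
  roles <- rep(c("signal", "confound", "mixed", "null"), counts)
  with_seed(derive_seed(config$seed, 104729L), {
    direct <- ifelse(roles %in% c("signal", "mixed"),
                     config$direct_effect * sample(c(-1, 1), p, replace = TRUE), 0)
    loadings <- matrix(0, config$n_confounds, p)
    conf_cols <- roles %in% c("confound", "mixed")
    if (any(conf_cols)) {
      loadings[, conf_cols] <- config$confound_effect *
        sample(c(-1, 1), config$n_confounds * sum(conf_cols), replace = TRUE)
    }
    list(roles = roles, direct = direct, loadings = loadings)
  })
}

sample_from_structure <- function(config, struct, n, data_seed, shift = NULL) {
  shift <- shift %||% shift_config()
  c_mean <- rep_len(shift$confound_mean_shift, config$n_confounds)
  c_sds <- rep_len(shift$confound_sd_scale, config$n_confounds)
  with_seed(data_seed, {
    n1 <- largest_remainder(c(config$class_balance, 1 - config$class_balance), n)[1]
    n1 <- max(1L, min(n - 1L, n1))
    y <- integer(n)
    y[sample.int(n, n1)] <- 1L
    ypm <- 2 * y - 1
    class_shift <- c(config$confound_class_shift + shift$target_confound_shift,
                     config$secondary_class_shift,
                     rep(0, max(0, config$n_confounds - 2)))[seq_len(config$n_confounds)]
    Z <- matrix(stats::rnorm(n * config$n_confounds), n)
    Z <- Z + outer(ypm / 2, class_shift)
    Z <- sweep(sweep(Z, 2, c_sds, "*"), 2, c_mean, "+")
    X <- outer(ypm, struct$direct) +
      Z %*% (shift$confound_effect_scale * struct$loadings) +
      config$noise_sd * matrix(stats::rnorm(n * config$n_features), n)
    X <- shift$feature_scale * X
    colnames(X) <- paste0("feat_", seq_len(config$n_features))
    colnames(Z) <- c("size", "age",
                     paste0("conf_", seq_len(max(0, config$n_confounds - 2)) + 2))[
                       seq_len(config$n_confounds)]
    ds <- confound_dataset(X, Z, y, feature_roles = struct$roles)
    attr(ds, "config") <- unclass(config)
    ds
  })
}

#' Generate a confounded dataset with known ground truth
#'
#' Draws a binary target with fixed class counts, Gaussian confounds of which
#' the first is shifted between classes by `confound_class_shift` (in
#' within-class SD units), and features built as
#' `direct_effect * (±1 target) + loadings' * confounds + noise`, with each
#' feature's role (signal-only / confound-only / mixed / null) recorded as
#' ground-truth metadata in `feature_roles`.
#'
#' @param config a [synthetic_config()].
#' @return a [confound_dataset()] with `feature_roles` metadata and the
#'   generating config stored as an attribute.
#' @export
#' @examples
#' ds <- generate_confounded_dataset(synthetic_config(n_samples = 50,
#'                                                    n_features = 10))
#' table(ds$feature_roles)
generate_confounded_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  struct <- generator_structure(config)
  sample_from_structure(config, struct, config$n_samples,
                        data_seed = derive_seed(config$seed, 2L))
}

#' Generate a shifted out-of-sample cohort from the same generative family
#'
#' Uses the same feature architecture (roles, loading signs) as
#' [generate_confounded_dataset()] with the same `config`, but modifies
#' confound means/SDs, confound-to-feature coefficient strength, feature
#' scale and class-confound coupling per `shift`. With the default (identity)
#' shift the cohort is a fresh draw from the base distribution.
#'
#' @param config the base [synthetic_config()].
#' @param shift a [shift_config()].
#' @param n_oos number of out-of-sample rows.
#' @return a [confound_dataset()].
#' @export
generate_shifted_oos <- function(config, shift = shift_config(), n_oos = 200) {
  stopifnot(inherits(config, "synthetic_config"), inherits(shift, "shift_config"))
  if (n_oos < 2) stop2("n_oos must be >= 2")
  struct <- generator_structure(config)
  sample_from_structure(config, struct, as.integer(n_oos),
                        data_seed = derive_seed(config$seed, 7919L),
                        shift = shift)
}

#' Generate toy ROI-grouped voxel time-series
#'
#' Each ROI's voxels share a latent time course (strength `shared_signal_sd`)
#' plus independent Gaussian noise; ROI latents can be correlated through
#' `roi_cor`. Intended as a fixture for the regional-homogeneity and
#' functional-connectivity feature-extraction formulas, not as a realistic
#' fMRI simulator (no autocorrelation, motion or atlas geometry).
#'
#' @param n_rois number of ROIs (>= 2).
#' @param voxels_per_roi voxels per ROI (>= 2).
#' @param n_timepoints time points (>= 3 for downstream concordance).
#' @param shared_signal_sd SD of the shared latent component (0 = independent
#'   voxels).
#' @param noise_sd SD of voxel-level noise (0 = identical voxels per ROI).
#' @param seed integer seed.
#' @param roi_cor optional `n_rois x n_rois` correlation matrix for the ROI
#'   latents (default: independent).
#' @return an object of class `roi_timeseries`: a named list of
#'   `voxels_per_roi x n_timepoints` matrices, one per ROI.
#' @export
generate_roi_timeseries <- function(n_rois, voxels_per_roi, n_timepoints,
                                    shared_signal_sd = 1, noise_sd = 1,
                                    seed = 1, roi_cor = NULL) {
  if (n_rois < 2 || voxels_per_roi < 2 || n_timepoints < 2) {
    stop2("n_rois, voxels_per_roi and n_timepoints must all be >= 2")
  }
  if (shared_signal_sd < 0 || noise_sd < 0) stop2("SDs must be >= 0")
  if (shared_signal_sd == 0 && noise_sd == 0) {
    stop2("at least one of shared_signal_sd, noise_sd must be positive")
  }
  with_seed(seed, {
    L <- matrix(stats::rnorm(n_rois * n_timepoints), n_rois)
    if (!is.null(roi_cor)) {
      if (!isTRUE(all.equal(dim(roi_cor), c(n_rois, n_rois)))) {
        stop2("roi_cor must be n_rois x n_rois")
      }
      L <- t(chol(roi_cor)) %*% L
    }
    out <- lapply(seq_len(n_rois), function(r) {
      shared <- matrix(rep(shared_signal_sd * L[r, ], each = voxels_per_roi),
                       voxels_per_roi)
      shared + noise_sd * matrix(stats::rnorm(voxels_per_roi * n_timepoints),
                                 voxels_per_roi)
    })
    names(out) <- paste0("ROI_", seq_len(n_rois))
    structure(out, class = "roi_timeseries")
  })
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d ROIs, %d voxels x %d timepoints each\n",
              length(x), nrow(x[[1]]), ncol(x[[1]])))
  invisible(x)
}
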