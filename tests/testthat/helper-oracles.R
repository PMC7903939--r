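# Independent oracles used to validate the production code paths. These are
# deliberately naive / textbook implementations, kept separate from anything
# in R/.

# Residual maker via the explicit projection matrix I - A (A'A)^+ A'.
oracle_projection_residuals <- function(X, Z) {
  A <- cbind(1, Z)
  P <- A %*% MASS_ginv(A) # hat matrix with pseudo-inverse
  (diag(nrow(A)) - P) %*% X
}

# Small Moore-Penrose pseudo-inverse (ginv without loading MASS namespace
# into the tests' search path).
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > max(s$d) * tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Brute-force AUC: loop over all positive-negative pairs, ties worth 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Textbook NIPALS PLS1 on centered data: iterative weight extraction with
# X and y deflation, coefficients via B = W (P'W)^-1 q. Written directly
# from the algorithm description, independent of the package's path code.
oracle_nipals_pls1 <- function(X, y, K) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(X)
  W <- matrix(0, p, K); P <- matrix(0, p, K); q <- numeric(K)
  for (k in seq_len(K)) {
    w <- t(Xc) %*% yc
    w <- w / sqrt(sum(w^2))
    t_ <- Xc %*% w
    p_ <- t(Xc) %*% t_ / sum(t_^2)
    q[k] <- sum(yc * t_) / sum(t_^2)
    Xc <- Xc - t_ %*% t(p_)
    yc <- yc - q[k] * t_
    W[, k] <- w; P[, k] <- p_
  }
  B <- W %*% solve(t(P) %*% W) %*% q
  list(weights = as.numeric(B),
       intercept = mean(y) - sum(colMeans(X) * B))
}

# Permutation null for Kendall's W: permute each voxel's series independently.
oracle_w_permutation_null <- function(voxel_ts, n_draws, seed = 1) {
  set.seed(seed)
  replicate(n_draws, {
    perm <- t(apply(voxel_ts, 1, sample))
    reho_kendalls_w(perm)
  })
}

# Mean-Spearman identity for Kendall's W (valid without ties):
# W = ((K-1) * mean pairwise Spearman rho + 1) / K.
oracle_w_from_spearman <- function(voxel_ts) {
  K <- nrow(voxel_ts)
  rho <- cor(t(voxel_ts), method = "spearman")
  mean_rho <- mean(rho[lower.tri(rho)])
  ((K - 1) * mean_rho + 1) / K
}

# A standard mixed-signal dataset used by several suites: direct target
# signal plus a confound path, at the study-condition scales.
mixed_signal_config <- function(seed, n = 300, p = 100) {
  synthetic_config(
    n_samples = n, n_features = p, confound_class_shift = 1.5,
    direct_effect = 0.3, confound_effect = 1,
    fractions = c(signal = 0.2, confound = 0.3, mixed = 0.2, null = 0.3),
    noise_sd = 1, seed = seed
  )
}

# Pure-confound dataset: the only path from target to features runs through
# confound 1.
pure_confound_config <- function(seed, n = 300, p = 100) {
  synthetic_config(
    n_samples = n, n_features = p, confound_class_shift = 1.5,
    direct_effect = 0, confound_effect = 1,
    fractions = c(signal = 0, confound = 0.7, mixed = 0, null = 0.3),
    noise_sd = 1, seed = seed
  )
}

fast_cv <- function(seed = 0, folds = 5, repeats = 2) {
  cv_scheme(n_folds = folds, n_repeats = repeats, seed = seed)
}

small_grid_ridge <- function() {
  estimator_spec("ridge", grid = 10^seq(-2, 3), inner_folds = 5)
}
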