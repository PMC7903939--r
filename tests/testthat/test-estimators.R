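test_that("ridge hits its closed-form landmarks", {
  # scalar toy: centered x = (-1,0,1), y = (1,2,3); slope = 2/(2+1) = 2/3,
  # intercept = ybar - xbar*slope = 2 - 2*(2/3) = 2/3
  d <- fit_ridge(cbind(x = c(1, 2, 3)), c(1, 2, 3), lambda = 1)
  expect_equal(unname(d$weights), 2 / 3, tolerance = 1e-12)
  expect_equal(d$intercept, 2 / 3, tolerance = 1e-12)
  # fitted values from the closed form
  expect_equal(predict_scores(d, cbind(x = c(1, 2, 3))),
               2 / 3 + 2 / 3 * c(1, 2, 3), tolerance = 1e-12)

  # lambda = 0 on full-rank X equals OLS
  set.seed(21)
  X <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(30)
  d0 <- fit_ridge(X, y, 0)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  expect_lt(max(abs(d0$weights - ols[-1])), 1e-8)
  expect_lt(abs(d0$intercept - ols[1]), 1e-8)

  # infinite-penalty limit: slopes vanish, predictions collapse to the mean
  dinf <- fit_ridge(X, y, 1e12)
  expect_lt(max(abs(dinf$weights)), 1e-8)
  expect_equal(predict_scores(dinf, X), rep(mean(y), 30), tolerance = 1e-6)

  expect_error(fit_ridge(X, y, -1), "lambda")
})

test_that("ridge agrees with glmnet and shrinks monotonically", {
  skip_if_not_installed("glmnet")
  set.seed(33)
  n <- 40
  X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rnorm(n)
  for (lam in c(0.5, 2, 10)) {
    d <- fit_ridge(X, y, lam)
    # glmnet's ridge objective is (1/2n)RSS + lambda/2 ||w||^2 on
    # standardize=FALSE; its lambda maps to ours via lambda_glmnet = lam/n.
    g <- glmnet::glmnet(X, y, alpha = 0, lambda = lam / n,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14)
    # glmnet solves the same objective (lambda scaled by 1/n) iteratively;
    # agreement is limited by its coordinate-descent accuracy
    expect_lt(max(abs(as.numeric(g$beta) - d$weights)), 5e-3)
  }
  # norm monotonicity in lambda
  lams <- c(0.01, 0.1, 1, 10, 100)
  norms <- sapply(lams, function(l) sqrt(sum(fit_ridge(X, y, l)$weights^2)))
  expect_true(all(diff(norms) <= 1e-12))
  # dual (p > n) route consistent with an explicit p x p solve
  Xp <- matrix(rnorm(15 * 40), 15, dimnames = list(NULL, paste0("f", 1:40)))
  yp <- rnorm(15)
  dd <- fit_ridge(Xp, yp, 3)
  Xc <- scale(Xp, scale = FALSE)
  w_primal <- solve(crossprod(Xc) + 3 * diag(40), crossprod(Xc, yp - mean(yp)))
  expect_lt(max(abs(dd$weights - as.numeric(w_primal))), 1e-8)
})

test_that("an all-zero feature column never changes ridge predictions", {
  set.seed(55)
  X <- matrix(rnorm(25 * 4), 25, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rnorm(25)
  d <- fit_ridge(X, y, 2)
  X0 <- cbind(X, zero = 0)
  d0 <- fit_ridge(X0, y, 2)
  expect_equal(predict_scores(d0, X0), predict_scores(d, X), tolerance = 1e-10)
})

test_that("PLS1 matches textbook NIPALS and the full-rank OLS identity", {
  set.seed(12)
  for (i in 1:8) {
    X <- matrix(rnorm(20 * 8), 20, dimnames = list(NULL, paste0("f", 1:8)))
    y <- rnorm(20)
    for (k in c(1, 3, 8)) {
      mine <- fit_pls(X, y, k)
      ref <- oracle_nipals_pls1(X, y, k)
      expect_lt(max(abs(mine$weights - ref$weights)), 1e-6)
      expect_lt(abs(mine$intercept - ref$intercept), 1e-6)
    }
    # k = rank(X centered) reproduces OLS predictions
    full <- fit_pls(X, y, 8)
    ols_fit <- lm.fit(cbind(1, X), y)$fitted.values
    expect_lt(max(abs(predict_scores(full, X) - ols_fit)), 1e-6)
  }
  # p = 1 reduces to simple linear regression
  x1 <- cbind(x = rnorm(15))
  y1 <- rnorm(15)
  slm <- lm.fit(cbind(1, x1), y1)$coefficients
  p1 <- fit_pls(x1, y1, 1)
  expect_equal(unname(p1$weights), unname(slm[2]), tolerance = 1e-10)

  # zero covariance with every centered column: zero weight vector
  Xz <- cbind(a = rep(c(-1, 1), 8), b = rep(c(1, -1), 8))
  yz <- rep(c(-1, -1, 1, 1), 4) # orthogonal to both columns
  stopifnot(abs(sum(Xz[, 1] * yz)) < 1e-12)
  pz <- fit_pls(Xz, yz, 2)
  expect_equal(unname(pz$weights), c(0, 0))

  expect_error(fit_pls(x1, y1, 0), "n_components")
  expect_error(fit_pls(x1, y1, 5), "n_components")
})

test_that("score prediction is linear and shape-checked", {
  d <- structure(list(weights = c(a = 1, b = 2), intercept = 0.5,
                      kind = "ridge", hyperparameter = 0),
                 class = "linear_decoder")
  X <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(predict_scores(d, X), c(1.5, 2.5))
  d2 <- d
  d2$weights["b"] <- 4
  expect_equal(predict_scores(d2, X) - predict_scores(d, X), c(0, 2))
  dz <- d
  dz$weights[] <- 0
  expect_equal(predict_scores(dz, X), c(0.5, 0.5))
  expect_error(predict_scores(d, cbind(a = 1)), "mismatch")
})

test_that("inner-CV tuning picks sensible hyperparameters", {
  # single-element grid short-circuits
  set.seed(3)
  X <- matrix(rnorm(40 * 5), 40, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(0:1, 20)
  expect_equal(tune_hyperparameter(X, y, estimator_spec("ridge", grid = 7))$value, 7)

  # pure-noise p >> n data: the stronger penalty wins almost always
  sel <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(40 * 200), 40, dimnames = list(NULL, paste0("f", 1:200)))
    yn <- rep(0:1, 20)
    tune_hyperparameter(Xn, yn, estimator_spec("ridge", grid = c(1e-3, 1)),
                        seed = s)$value
  }, numeric(1))
  expect_gte(mean(sel == 1), 0.8)

  # exact ties resolve to the stronger regularization
  Xc <- cbind(f = rep(0, 20)) # constant feature: every lambda ties
  yc <- rep(0:1, 10)
  expect_equal(tune_hyperparameter(Xc, yc,
                                   estimator_spec("ridge", grid = c(0.1, 10)),
                                   seed = 1)$value, 10)
  expect_error(estimator_spec("ridge", grid = numeric(0)), "non-empty")
})

test_that("decoders serialize losslessly", {
  set.seed(61)
  X <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, paste0("f", 1:3)))
  d <- fit_ridge(X, rnorm(20), 1.5)
  d2 <- decoder_from_json(decoder_to_json(d))
  expect_equal(predict_scores(d2, X), predict_scores(d, X), tolerance = 1e-12)
  expect_identical(d2$kind, "ridge")
  expect_equal(d2$hyperparameter, 1.5)
})
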