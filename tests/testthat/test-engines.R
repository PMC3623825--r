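# Engines are exercised through fit_neighbor_regression on centered data; the
# internal kernels are reached directly where the contract is about them.

make_design <- function(n, q, seed, beta = NULL) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * q), n, q)
    if (is.null(beta)) beta <- rnorm(q)
    y <- drop(X %*% beta + rnorm(n))
    list(X = scale(X, scale = FALSE), y = y - mean(y), beta = beta)
  })
}

test_that("ols refuses saturated designs and matches lm otherwise", {
  d <- make_design(50, 5, 1)
  eng <- regression_engine("ols")
  fit <- pcorsel:::fit_engine(d$y, d$X, eng)
  expect_equal(unname(fit$coefficients),
               unname(coef(lm(d$y ~ d$X - 1))), tolerance = 1e-10)
  d2 <- make_design(6, 8, 2)
  expect_error(pcorsel:::fit_engine(d2$y, d2$X, eng), "regularized")
})

test_that("ridge shrinks monotonically and approaches ols as the penalty vanishes", {
  d <- make_design(60, 4, 3)
  ols <- unname(coef(lm(d$y ~ d$X - 1)))
  b_small <- drop(pcorsel:::ridge_path(d$y, d$X, 1e-10))
  b_large <- drop(pcorsel:::ridge_path(d$y, d$X, 1e8))
  expect_equal(unname(b_small), ols, tolerance = 1e-6)
  expect_lt(sum(b_large^2), 1e-6)
  # closed form check against the normal equations at a middling penalty
  lam <- 2.5
  direct <- solve(crossprod(d$X) + lam * diag(4), crossprod(d$X, d$y))
  expect_equal(unname(drop(pcorsel:::ridge_path(d$y, d$X, lam))),
               unname(drop(direct)), tolerance = 1e-10)
})

test_that("cross-validated engines are deterministic given the engine seed", {
  d <- make_design(40, 6, 4)
  for (name in c("ridge_cv", "pls", "lasso", "adalasso")) {
    eng <- regression_engine(name, seed = 99)
    f1 <- pcorsel:::fit_engine(d$y, d$X, eng)
    f2 <- pcorsel:::fit_engine(d$y, d$X, eng)
    expect_identical(f1, f2, info = name)
  }
})

test_that("analytic ridge penalty reproduces the plug-in formula", {
  # orthonormal centered design with beta_ls = (1, 1) and s^2 = 1:
  # lambda = q * s^2 / ||beta||^2 = 2 / 2 = 1
  n <- 23
  base <- withr::with_seed(7, matrix(rnorm(n * 3), n, 3))
  Q <- qr.Q(qr(cbind(1, base)))[, 2:4] # orthonormal, orthogonal to intercept
  X <- Q[, 1:2]
  resid <- Q[, 3] * sqrt(n - 1 - 2) # RSS = n - 3  =>  s^2 = 1
  y <- drop(X %*% c(1, 1)) + resid
  expect_equal(analytic_ridge_parameter(y, X), 1, tolerance = 1e-8)

  # perfect fit returns the floor
  y_exact <- drop(X %*% c(2, -1))
  expect_equal(analytic_ridge_parameter(y_exact, X), 1e-8)
  expect_gte(analytic_ridge_parameter(y, X, lambda_floor = 1e-8), 1e-8)
})

test_that("analytic ridge penalty handles rank-deficient designs via minimum-norm ls", {
  d <- make_design(8, 15, 5)
  lam <- analytic_ridge_parameter(d$y, d$X)
  expect_true(is.finite(lam) && lam > 0)
  # oracle: explicit pseudoinverse computation of the same formula
  Xc <- scale(d$X, scale = FALSE)
  yc <- d$y - mean(d$y)
  beta <- drop(MASS::ginv(Xc) %*% yc)
  rss <- sum((yc - Xc %*% beta)^2)
  rank_x <- qr(Xc)$rank
  s2 <- rss / max(nrow(Xc) - 1 - rank_x, 1)
  lam_oracle <- max(ncol(Xc) * s2 / sum(beta^2), 1e-8)
  expect_equal(lam, lam_oracle, tolerance = 1e-6)
})

test_that("pls1 kernel agrees with an independent pls implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_design(40, 5, 6)
  paths <- pcorsel:::pls1_paths(d$y, d$X, 3)
  colnames(d$X) <- paste0("x", 1:5)
  ref <- mixOmics::pls(d$X, d$y, ncomp = 3, scale = FALSE, mode = "regression")
  B_ref <- predict(ref, d$X)$B.hat
  for (k in 1:3) {
    expect_equal(unname(paths[, k]), unname(B_ref[, 1, k]), tolerance = 1e-8)
  }
})

test_that("full-rank pls with all components recovers least squares", {
  d <- make_design(50, 4, 8)
  paths <- pcorsel:::pls1_paths(d$y, d$X, 4)
  expect_equal(unname(paths[, 4]),
               unname(coef(lm(d$y ~ d$X - 1))), tolerance = 1e-8)
})

test_that("lasso engines recover a strong sparse signal and drop null covariates", {
  d <- make_design(200, 6, 9, beta = c(2, -2, 0, 0, 1.5, 0))
  for (name in c("lasso", "adalasso")) {
    eng <- regression_engine(name, seed = 2)
    fit <- pcorsel:::fit_engine(d$y, d$X, eng)
    expect_equal(unname(sign(fit$coefficients[c(1, 2, 5)])), c(1, -1, 1),
                 info = name)
    expect_lt(max(abs(fit$coefficients[c(3, 4, 6)])), 0.2)
  }
})

test_that("single-covariate lasso uses the exact soft-threshold solution", {
  d <- make_design(100, 1, 10, beta = 1.5)
  eng <- regression_engine("lasso", seed = 3)
  fit <- pcorsel:::fit_engine(d$y, d$X, eng)
  ols <- sum(d$X * d$y) / sum(d$X^2)
  expect_lt(abs(fit$coefficients - ols), 0.2)
  expect_lte(abs(fit$coefficients), abs(ols)) # shrinkage never inflates
})

test_that("engine validation rejects bad configurations", {
  expect_error(regression_engine("ridge_cv", cv_folds = 1), "cv_folds")
  expect_error(regression_engine("ridge_cv", lambda_grid = numeric(0)), "lambda_grid")
  expect_error(regression_engine("nonsense"), "arg")
})
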