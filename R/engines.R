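#' Regression engines for neighbor regressions
#'
#' The graph-constrained estimator regresses each variable on its graph
#' neighbors; the engine decides how those regressions are fitted. When a node
#' has more neighbors than observations, least squares is unavailable and a
#' regularized engine must be used.
#'
#' Engines:
#' \describe{
#'   \item{`ols`}{ordinary least squares; errors when a node has >= n-1
#'     neighbors.}
#'   \item{`ridge_cv`}{ridge regression; penalty chosen by seeded K-fold
#'     cross-validation over a logarithmic grid.}
#'   \item{`ridge_analytic`}{ridge regression with the Hoerl–Kennard–Baldwin
#'     plug-in penalty lambda = q * s^2 / ||beta_ls||^2 (no cross-validation);
#'     see [analytic_ridge_parameter()].}
#'   \item{`pls`}{partial least squares (PLS1, orthogonal scores); number of
#'     components chosen by cross-validation.}
#'   \item{`lasso`}{lasso via glmnet; lambda chosen by cross-validation.}
#'   \item{`adalasso`}{adaptive lasso: covariate weights 1/|beta_ridge| from a
#'     cross-validated ridge initial fit (gamma = 1); covariates with zero
#'     initial coefficient are dropped.}
#' }
#'
#' All engines operate on column-centered data and fit no intercept. Ridge and
#' PLS use the covariates on their original scale; lasso and adaptive lasso
#' standardize internally and back-transform, so penalties are comparable
#' across covariates.
#'
#' @param name Engine name, one of `"ols"`, `"ridge_cv"`, `"ridge_analytic"`,
#'   `"pls"`, `"lasso"`, `"adalasso"`.
#' @param cv_folds Number of cross-validation folds (>= 2, default 10).
#' @param seed Integer seed controlling fold assignment (and nothing else);
#'   fits are deterministic given the engine seed.
#' @param lambda_grid Ridge penalty grid (default 25 log-spaced points in
#'   1e-4..1e4).
#' @param ncomp_max Upper bound on PLS components (further capped at
#'   min(q, n_train - 1)).
#' @param lambda_floor Lower bound for the analytic ridge penalty, returned
#'   when the least-squares fit is perfect.
#' @return A `regression_engine` object.
#' @examples
#' regression_engine("ridge_cv", cv_folds = 5, seed = 42)
#' @export
regression_engine <- function(name = c("ols", "ridge_cv", "ridge_analytic",
                                       "pls", "lasso", "adalasso"),
                              cv_folds = 10L, seed = 1L,
                              lambda_grid = 10^seq(-4, 4, length.out = 25),
                              ncomp_max = 15L, lambda_floor = 1e-8) {
  name <- match.arg(name)
  if (!is.numeric(cv_folds) || cv_folds < 2) abort("`cv_folds` must be >= 2.")
  if (length(lambda_grid) < 1L || any(lambda_grid <= 0)) {
    abort("`lambda_grid` must be a non-empty vector of positive penalties.")
  }
  structure(
    list(name = name, cv_folds = as.integer(cv_folds), seed = as.integer(seed),
         lambda_grid = sort(lambda_grid), ncomp_max = as.integer(ncomp_max),
         lambda_floor = lambda_floor),
    class = "regression_engine"
  )
}

#' @export
print.regression_engine <- function(x, ...) {
  cat(sprintf("<regression_engine> %s (cv_folds = %d, seed = %d)\n",
              x$name, x$cv_folds, x$seed))
  invisible(x)
}

# Reseed an engine deterministically (used per iteration of the iterative
# procedure so folds differ across iterations but traces are reproducible).
reseed_engine <- function(engine, offset) {
  engine$seed <- (engine$seed + as.integer(offset)) %% .Machine$integer.max
  engine
}

# --- fitting kernels ---------------------------------------------------------
# All kernels take a centered response y and centered covariate matrix X and
# return list(coefficients, hyperparameter).

fit_engine <- function(y, X, engine) {
  q <- ncol(X)
  if (q == 0L) {
    return(list(coefficients = stats::setNames(numeric(0), character(0)),
                hyperparameter = NA_real_))
  }
  out <- switch(engine$name,
    ols            = fit_ols(y, X),
    ridge_cv       = fit_ridge_cv(y, X, engine),
    ridge_analytic = fit_ridge_analytic(y, X, engine),
    pls            = fit_pls_cv(y, X, engine),
    lasso          = fit_lasso(y, X, engine, adaptive = FALSE),
    adalasso       = fit_lasso(y, X, engine, adaptive = TRUE)
  )
  names(out$coefficients) <- colnames(X)
  if (any(!is.finite(out$coefficients))) {
    abort(sprintf("Engine `%s` produced non-finite coefficients.", engine$name))
  }
  out
}

fit_ols <- function(y, X) {
  n <- nrow(X)
  if (ncol(X) >= n - 1L) {
    abort(paste0(
      "ols engine: ", ncol(X), " covariates with only ", n, " observations; ",
      "use a regularized engine (ridge_cv, ridge_analytic, pls, lasso, adalasso)."
    ))
  }
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  b[is.na(b)] <- 0 # exactly collinear covariates contribute nothing
  list(coefficients = b, hyperparameter = NA_real_)
}

# Ridge path via SVD: beta(lambda) = V diag(d / (d^2 + lambda)) U'y.
ridge_path <- function(y, X, lambdas) {
  sv <- svd(X)
  uty <- drop(crossprod(sv$u, y))
  sapply(lambdas, function(l) drop(sv$v %*% (sv$d / (sv$d^2 + l) * uty)))
}

fit_ridge_cv <- function(y, X, engine) {
  n <- nrow(X)
  folds <- min(engine$cv_folds, n)
  fold_id <- cv_fold_assignment(n, folds, engine$seed)
  lambdas <- engine$lambda_grid
  cv_err <- numeric(length(lambdas))
  for (k in seq_len(folds)) {
    test <- fold_id == k
    B <- ridge_path(y[!test], X[!test, , drop = FALSE], lambdas)
    B <- matrix(B, ncol = length(lambdas))
    resid <- y[test] - X[test, , drop = FALSE] %*% B
    cv_err <- cv_err + colSums(resid^2)
  }
  best <- lambdas[which.min(cv_err)]
  beta <- drop(ridge_path(y, X, best))
  list(coefficients = beta, hyperparameter = best)
}

fit_ridge_analytic <- function(y, X, engine) {
  lambda <- hkb_lambda(y, X, lambda_floor = engine$lambda_floor)
  beta <- drop(ridge_path(y, X, lambda))
  list(coefficients = beta, hyperparameter = lambda)
}

# Hoerl-Kennard-Baldwin plug-in penalty, q * s^2 / ||beta_ls||^2, with the
# minimum-norm least-squares fit when rank-deficient. Defined for any q >= 1;
# the exported analytic_ridge_parameter() adds the user-facing preconditions.
hkb_lambda <- function(y, X, lambda_floor = 1e-8) {
  ls <- min_norm_ls(y, X)
  rss <- sum((y - X %*% ls$beta)^2)
  df <- max(nrow(X) - 1L - ls$rank, 1L)
  s2 <- rss / df
  bnorm2 <- sum(ls$beta^2)
  if (s2 <= 0 || bnorm2 <= 0) return(lambda_floor)
  max(ncol(X) * s2 / bnorm2, lambda_floor)
}

# Minimum-norm least squares via the SVD pseudoinverse (handles q >= n).
min_norm_ls <- function(y, X, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1L]
  beta <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep])
  list(beta = drop(beta), rank = sum(keep))
}

# PLS1 with orthogonal scores. Returns the coefficient paths for 1..ncomp
# components as a q x ncomp matrix (column k = coefficients using k comps).
pls1_paths <- function(y, X, ncomp) {
  q <- ncol(X)
  Wm <- matrix(0, q, ncomp)
  Pm <- matrix(0, q, ncomp)
  qv <- numeric(ncomp)
  Xk <- X
  used <- 0L
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xk, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xk %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p <- drop(crossprod(Xk, t)) / tt
    Wm[, k] <- w
    Pm[, k] <- p
    qv[k] <- sum(y * t) / tt
    Xk <- Xk - tcrossprod(t, p)
    used <- k
  }
  if (used == 0L) return(matrix(0, q, 1L))
  B <- matrix(0, q, used)
  for (k in seq_len(used)) {
    Wk <- Wm[, seq_len(k), drop = FALSE]
    Pk <- Pm[, seq_len(k), drop = FALSE]
    # (P'W) is unit upper-triangular in exact arithmetic
    B[, k] <- Wk %*% solve(crossprod(Pk, Wk), qv[seq_len(k)])
  }
  B
}

fit_pls_cv <- function(y, X, engine) {
  n <- nrow(X)
  q <- ncol(X)
  folds <- min(engine$cv_folds, n)
  fold_id <- cv_fold_assignment(n, folds, engine$seed)
  ncomp_max <- max(1L, min(engine$ncomp_max, q,
                           n - ceiling(n / folds) - 1L))
  cv_err <- rep(0, ncomp_max)
  cv_cnt <- rep(0L, ncomp_max)
  for (k in seq_len(folds)) {
    test <- fold_id == k
    B <- pls1_paths(y[!test], X[!test, , drop = FALSE], ncomp_max)
    resid <- y[test] - X[test, , drop = FALSE] %*% B
    m <- ncol(B)
    cv_err[seq_len(m)] <- cv_err[seq_len(m)] + colSums(resid^2)
    cv_cnt[seq_len(m)] <- cv_cnt[seq_len(m)] + 1L
  }
  avail <- cv_cnt == max(cv_cnt)
  best <- which(avail)[which.min(cv_err[avail] / cv_cnt[avail])]
  B <- pls1_paths(y, X, best)
  list(coefficients = B[, ncol(B)], hyperparameter = best)
}

fit_lasso <- function(y, X, engine, adaptive = FALSE) {
  n <- nrow(X)
  folds <- min(engine$cv_folds, n)
  fold_id <- cv_fold_assignment(n, folds, engine$seed)
  penalty <- rep(1, ncol(X))
  keep <- rep(TRUE, ncol(X))
  if (adaptive) {
    init <- fit_ridge_cv(y, X, engine)$coefficients
    keep <- abs(init) > 1e-10
    if (!any(keep)) {
      return(list(coefficients = rep(0, ncol(X)), hyperparameter = NA_real_))
    }
    penalty <- 1 / abs(init[keep])
  }
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) == 1L) {
    b <- lasso_univariate(y, drop(Xk), fold_id, penalty)
    beta <- rep(0, ncol(X))
    beta[keep] <- b$beta
    return(list(coefficients = beta, hyperparameter = b$lambda))
  }
  cv <- glmnet::cv.glmnet(Xk, y, foldid = fold_id, intercept = FALSE,
                          standardize = TRUE, penalty.factor = penalty)
  beta_k <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  beta <- rep(0, ncol(X))
  beta[keep] <- beta_k
  list(coefficients = beta, hyperparameter = cv$lambda.min)
}

# glmnet needs >= 2 covariates; single-covariate lasso has the exact
# soft-threshold solution, cross-validated over a glmnet-style threshold path
# (the penalty factor is folded into the effective threshold).
lasso_univariate <- function(y, x, fold_id, penalty = 1) {
  n <- length(y)
  tmax <- abs(sum(x * y)) / n
  if (tmax < 1e-12) return(list(beta = 0, lambda = NA_real_))
  thresh <- tmax * 10^seq(0, -4, length.out = 50)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  cv_err <- numeric(length(thresh))
  for (k in unique(fold_id)) {
    test <- fold_id == k
    xy <- sum(x[!test] * y[!test]) / sum(!test)
    xx <- sum(x[!test]^2) / sum(!test)
    b <- soft(xy, thresh) / xx
    cv_err <- cv_err + vapply(b, function(bi) sum((y[test] - bi * x[test])^2), 0)
  }
  best <- thresh[which.min(cv_err)]
  xy <- sum(x * y) / n
  xx <- sum(x^2) / n
  list(beta = soft(xy, best) / xx, lambda = best / penalty)
}
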