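#' Graph-constrained partial correlation estimation
#'
#' Estimates the partial correlation matrix of a Gaussian dataset under the
#' constraint that entries absent from a given independence graph are exactly
#' zero. Each variable is regressed on its graph neighbors only (the missing
#' covariates are the zero constraints), and for every edge (i, j) the partial
#' correlation is recovered from the two regression coefficients through the
#' classical identity
#' \deqn{\hat\rho_{ij} = \mathrm{sign}(\hat\beta_{ij})
#'   \sqrt{\hat\beta_{ij}\,\hat\beta_{ji}},}
#' while non-edges are written as literal zeros. With the complete graph and
#' least squares this reduces to the classical unconstrained estimator
#' obtained by normalizing the inverse sample covariance matrix.
#'
#' When the two coefficients of an edge disagree in sign the square root is
#' undefined; the entry is set to 0 and the pair is reported in the fit (and a
#' warning of class `pcorsel_discordant` is raised). Entries exceeding 1 in
#' absolute value after the square root (possible with regularized engines)
#' are clipped to ±1 with a warning of class `pcorsel_clipped`.
#'
#' @param data Dataset, samples in rows and variables in columns (data frame
#'   or numeric matrix with column names).
#' @param graph An [independence_graph] over the same variables (any order).
#' @param engine A [regression_engine()]; default cross-validated ridge.
#' @return A `pacose_fit` object: list with `pcor` (the estimated matrix),
#'   `graph` (in data column order), `engine`, `n`, `node_fits` (tibble of
#'   per-node neighbor counts and selected hyperparameters), `discordant`
#'   (tibble of sign-discordant pairs) and `clipped` (count). Use
#'   [tidy.pacose_fit()] for an edge-level tibble.
#' @examples
#' g <- random_graph(10, "erdos_renyi", density = 0.2, seed = 2)
#' m <- build_precision_model(g, seed = 2)
#' x <- sample_gaussian(m, n = 200, seed = 2)
#' fit <- pacose(x, m$graph, regression_engine("ols"))
#' fit$pcor[1:3, 1:3]
#' @export
pacose <- function(data, graph, engine = regression_engine("ridge_cv")) {
  X <- as_data_matrix(data)
  stopifnot(inherits(graph, "independence_graph"),
            inherits(engine, "regression_engine"))
  labels <- colnames(X)
  if (!setequal(labels, graph$nodes)) {
    abort("Variable names of `data` and node labels of `graph` must agree.")
  }
  graph <- reorder_graph(graph, labels)
  p <- length(labels)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance column(s): %s.",
                  paste(labels[sds == 0], collapse = ", ")))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)

  B <- matrix(0, p, p, dimnames = list(labels, labels))
  hyper <- rep(NA_real_, p)
  n_neigh <- integer(p)
  for (i in seq_len(p)) {
    nb <- graph$adjacency[i, ]
    n_neigh[i] <- sum(nb)
    if (!any(nb)) next
    fit <- tryCatch(
      fit_engine(Xc[, i], Xc[, nb, drop = FALSE], engine),
      error = function(e) {
        abort(sprintf("Engine failure at node `%s`: %s", labels[i],
                      conditionMessage(e)))
      }
    )
    B[i, nb] <- fit$coefficients
    hyper[i] <- fit$hyperparameter
  }

  comb <- combine_beta_matrix(B, graph$adjacency)
  if (nrow(comb$discordant) > 0L) {
    warn(sprintf("%d edge(s) had sign-discordant regression coefficients; set to 0.",
                 nrow(comb$discordant)),
         class = "pcorsel_discordant")
  }
  if (comb$clipped > 0L) {
    warn(sprintf("%d partial correlation(s) exceeded 1 in magnitude; clipped.",
                 comb$clipped),
         class = "pcorsel_clipped")
  }
  structure(
    list(pcor = comb$pcor, graph = graph, engine = engine, n = nrow(X),
         node_fits = tibble::tibble(node = labels, n_neighbors = n_neigh,
                                    hyperparameter = hyper),
         discordant = comb$discordant, clipped = comb$clipped),
    class = "pacose_fit"
  )
}

# Symmetrize a coefficient matrix into a partial correlation matrix under an
# adjacency constraint. B[i, j] = coefficient of j in the regression of i.
combine_beta_matrix <- function(B, adjacency) {
  labels <- colnames(B)
  p <- ncol(B)
  pcor <- diag(p)
  dimnames(pcor) <- dimnames(B)
  disc_i <- integer(0)
  disc_j <- integer(0)
  clipped <- 0L
  idx <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    prod_ij <- B[i, j] * B[j, i]
    if (prod_ij > 0) {
      r <- sign(B[i, j]) * sqrt(prod_ij)
      if (abs(r) > 1) {
        r <- sign(r)
        clipped <- clipped + 1L
      }
      pcor[i, j] <- pcor[j, i] <- r
    } else if (prod_ij < 0) {
      disc_i <- c(disc_i, i)
      disc_j <- c(disc_j, j)
    }
  }
  list(pcor = pcor, clipped = clipped,
       discordant = tibble::tibble(from = labels[disc_i], to = labels[disc_j]))
}

#' @export
print.pacose_fit <- function(x, ...) {
  cat(sprintf(
    "<pacose_fit> p = %d, n = %d, engine = %s, %d constrained edges\n",
    n_nodes(x$graph), x$n, x$engine$name, n_edges(x$graph)))
  invisible(x)
}

#' Single neighbor-restricted regression
#'
#' Fits the regression of one variable on its graph neighbors — the building
#' block of [pacose()] — and returns the coefficients. Data are column-centered
#' and the intercept is dropped.
#'
#' @inheritParams pacose
#' @param target Label of the response variable.
#' @return A `neighbor_fit`: list with `response_label`, `neighbor_labels`,
#'   `coefficients` (named, one per neighbor), `engine_used`,
#'   `selected_hyperparameter`.
#' @export
fit_neighbor_regression <- function(data, target, graph,
                                    engine = regression_engine("ols")) {
  X <- as_data_matrix(data)
  stopifnot(inherits(graph, "independence_graph"))
  labels <- colnames(X)
  if (!target %in% labels) abort(sprintf("Unknown target `%s`.", target))
  if (!setequal(labels, graph$nodes)) {
    abort("Variable names of `data` and node labels of `graph` must agree.")
  }
  graph <- reorder_graph(graph, labels)
  if (stats::sd(X[, target]) == 0) {
    abort(sprintf("Response column `%s` has zero variance.", target))
  }
  nb <- graph_neighbors(graph, target)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  fit <- fit_engine(Xc[, target], Xc[, nb, drop = FALSE], engine)
  structure(
    list(response_label = target, neighbor_labels = nb,
         coefficients = fit$coefficients, engine_used = engine$name,
         selected_hyperparameter = fit$hyperparameter),
    class = "neighbor_fit"
  )
}

#' Analytic (Hoerl–Kennard–Baldwin) ridge penalty
#'
#' Plug-in choice of the ridge penalty, lambda = q * s^2 / ||beta_ls||^2,
#' where q is the number of covariates, beta_ls the least-squares coefficients
#' (minimum-norm least squares when the design is rank-deficient) and s^2 the
#' residual variance. Replaces cross-validation when a deterministic,
#' perturbation-stable penalty is wanted, e.g. in network stability studies.
#'
#' @param response Numeric response vector (centered internally).
#' @param covariates Numeric covariate matrix, >= 2 columns, >= 3 rows.
#' @param lambda_floor Value returned when the least-squares fit is perfect
#'   (zero residual variance); also a hard lower bound.
#' @return A single positive penalty value.
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x %*% c(1, -1, 0.5) + rnorm(20)
#' analytic_ridge_parameter(y, x)
#' @export
analytic_ridge_parameter <- function(response, covariates, lambda_floor = 1e-8) {
  X <- as.matrix(covariates)
  y <- as.numeric(response)
  if (ncol(X) < 2L) abort("`covariates` must have at least 2 columns.")
  if (nrow(X) < 3L || length(y) != nrow(X)) {
    abort("Need at least 3 observations, matching `response` length.")
  }
  y <- y - mean(y)
  X <- scale(X, center = TRUE, scale = FALSE)
  hkb_lambda(y, X, lambda_floor = lambda_floor)
}

#' Rescale a partial correlation matrix to the precision scale
#'
#' Inverts the precision-to-partial-correlation normalization: given partial
#' variances v_i (the reciprocal diagonal of the precision matrix), returns
#' the matrix with Omega_ii = 1/v_i and Omega_ij = -rho_ij *
#' sqrt(Omega_ii * Omega_jj). The zero pattern of `pcor` is preserved, so a
#' graph-constrained estimate yields a precision matrix with the same
#' constraints.
#'
#' @param pcor A partial correlation matrix (or a `pacose_fit`).
#' @param partial_variances Vector of p positive partial variances.
#' @return A p x p precision-scale matrix.
#' @export
pcor_to_precision_scale <- function(pcor, partial_variances) {
  if (inherits(pcor, "pacose_fit")) pcor <- pcor$pcor
  pcor <- validate_pcor(pcor)
  p <- ncol(pcor)
  v <- as.numeric(partial_variances)
  if (length(v) != p || any(!is.finite(v)) || any(v <= 0)) {
    abort("`partial_variances` must be p positive numbers.")
  }
  d <- 1 / v
  omega <- -pcor * sqrt(tcrossprod(d))
  diag(omega) <- d
  dimnames(omega) <- dimnames(pcor)
  omega
}

# Validate the partial-correlation-matrix contract; returns the matrix.
validate_pcor <- function(pcor, tol = 1e-8) {
  if (!is.matrix(pcor) || nrow(pcor) != ncol(pcor)) {
    abort("`pcor` must be a square matrix.")
  }
  if (max(abs(pcor - t(pcor))) > tol) abort("`pcor` must be symmetric.")
  if (max(abs(diag(pcor) - 1)) > tol) abort("`pcor` must have unit diagonal.")
  if (max(abs(pcor)) > 1 + tol) abort("`pcor` entries must lie in [-1, 1].")
  pcor
}
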