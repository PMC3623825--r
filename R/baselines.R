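#' Normalize a precision matrix into partial correlations
#'
#' The classical transform rho_ij = -omega_ij / sqrt(omega_ii * omega_jj),
#' with unit diagonal. Any estimated precision matrix can be made comparable
#' to a graph-constrained partial correlation estimate this way.
#'
#' @param precision A symmetric positive definite matrix.
#' @return A partial correlation matrix with the same dimnames.
#' @examples
#' precision_to_pcor(matrix(c(2, -1, -1, 2), 2))
#' @export
precision_to_pcor <- function(precision) {
  if (!is.matrix(precision) || nrow(precision) != ncol(precision)) {
    abort("`precision` must be a square matrix.")
  }
  if (any(diag(precision) <= 0)) {
    abort("`precision` must have a positive diagonal.")
  }
  d <- sqrt(diag(precision))
  pcor <- -precision / tcrossprod(d)
  diag(pcor) <- 1
  dimnames(pcor) <- dimnames(precision)
  pcor
}

#' Shrinkage partial correlations (unconstrained baseline)
#'
#' Analytic shrinkage of the sample correlation matrix toward the identity
#' target, with the data-driven intensity of the Ledoit–Wolf / Schäfer–Strimmer
#' family, followed by inversion and the precision-to-partial-correlation
#' transform. Guaranteed invertible for any n >= 3, never graph-constrained;
#' serves as the agnostic reference method.
#'
#' @param data Dataset, samples in rows (data frame or matrix).
#' @return A partial correlation matrix with attribute `"shrinkage_intensity"`
#'   (the estimated weight on the identity target, in \[0, 1\]).
#' @export
shrinkage_pcor <- function(data) {
  X <- as_data_matrix(data)
  n <- nrow(X)
  if (n < 3L) abort("`data` needs at least 3 samples.")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance column(s): %s.",
                  paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  Z <- scale(X) # standardized columns
  R <- crossprod(Z) / (n - 1)
  # var-hat of each off-diagonal correlation from the products w_k = z_ki z_kj
  # (Schafer-Strimmer): Var(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2
  sum_w2 <- crossprod(Z^2)          # sum_k w_k^2
  sum_w <- crossprod(Z)             # sum_k w_k
  var_r <- n / (n - 1)^3 * (sum_w2 - sum_w^2 / n)
  off <- upper.tri(R)
  denom <- sum(R[off]^2)
  lambda <- if (denom > 0) min(1, max(0, sum(var_r[off]) / denom)) else 1
  R_shrunk <- (1 - lambda) * R
  diag(R_shrunk) <- 1
  pcor <- precision_to_pcor(solve(R_shrunk))
  attr(pcor, "shrinkage_intensity") <- lambda
  pcor
}

#' Covariance selection by iterative proportional fitting
#'
#' Computes the graph-constrained Gaussian maximum-likelihood covariance
#' estimate: the matrix agreeing with `sample_cov` on the diagonal and on
#' every graph edge whose inverse has exact zeros on all non-edges. Cyclic
#' iterative proportional fitting over the edge pairs (pairwise cliques) is
#' used; on decomposable graphs with edges in a running-intersection order it
#' converges in one sweep, otherwise it iterates until the largest discrepancy
#' on the constrained entries falls below `tol`. Non-convergence within
#' `max_sweeps` is flagged, not an error.
#'
#' @param sample_cov Symmetric positive definite sample covariance matrix.
#' @param graph An [independence_graph] over the same variables.
#' @param tol Convergence tolerance on the constrained covariance entries.
#' @param max_sweeps Maximum number of full passes over the edge set.
#' @return A `covariance_estimate`: list with `covariance`, `precision`
#'   (non-edges zeroed exactly), `converged`, `sweeps`, `max_discrepancy`,
#'   `method = "ipf"`.
#' @export
ipf_covariance_selection <- function(sample_cov, graph, tol = 1e-8,
                                     max_sweeps = 5000L) {
  stopifnot(inherits(graph, "independence_graph"))
  S <- as.matrix(sample_cov)
  p <- ncol(S)
  if (nrow(S) != p || max(abs(S - t(S))) > 1e-8) {
    abort("`sample_cov` must be a symmetric square matrix.")
  }
  if (is.null(colnames(S))) dimnames(S) <- list(graph$nodes, graph$nodes)
  if (!setequal(colnames(S), graph$nodes)) {
    abort("Variable names of `sample_cov` and `graph` must agree.")
  }
  graph <- reorder_graph(graph, colnames(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("`sample_cov` must be positive definite.")
  check_scalar_number(tol, "tol", 0, Inf, strict = TRUE)

  edges <- which(graph$adjacency & upper.tri(graph$adjacency), arr.ind = TRUE)
  if (nrow(edges) > 1L) {
    # visit edges in breadth-first discovery order: on a tree (or any
    # decomposable graph whose pairwise cliques then satisfy the running
    # intersection property) a single sweep reaches the constrained MLE
    bfs_order <- as.integer(igraph::bfs(as_igraph(graph), root = 1,
                                        unreachable = TRUE)$order)
    rk <- match(seq_len(p), bfs_order)
    edge_rank <- cbind(pmax(rk[edges[, 1L]], rk[edges[, 2L]]),
                       pmin(rk[edges[, 1L]], rk[edges[, 2L]]))
    edges <- edges[order(edge_rank[, 1L], edge_rank[, 2L]), , drop = FALSE]
  }
  K <- diag(1 / diag(S))
  dimnames(K) <- dimnames(S)
  converged <- nrow(edges) == 0L
  sweeps <- 0L
  disc <- 0
  while (!converged && sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    disc <- 0
    for (e in seq_len(nrow(edges))) {
      ij <- edges[e, ]
      # current marginal covariance on {i, j}: columns i, j of K^{-1}
      E <- matrix(0, p, 2L)
      E[cbind(ij, 1:2)] <- 1
      sigma_ij <- crossprod(E, solve(K, E))
      sigma_ij <- (sigma_ij + t(sigma_ij)) / 2
      disc <- max(disc, max(abs(sigma_ij - S[ij, ij])))
      K[ij, ij] <- K[ij, ij] + solve(S[ij, ij]) - solve(sigma_ij)
    }
    converged <- disc < tol
  }
  K[!graph$adjacency & !diag(p)] <- 0 # exact zeros off the graph
  K <- (K + t(K)) / 2
  sigma <- solve(K)
  sigma <- (sigma + t(sigma)) / 2
  structure(
    list(covariance = sigma, precision = K, converged = converged,
         sweeps = sweeps, max_discrepancy = disc, method = "ipf"),
    class = "covariance_estimate"
  )
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("<covariance_estimate> %s, p = %d, converged = %s (%d sweep(s))\n",
              x$method, ncol(x$covariance), x$converged, x$sweeps))
  invisible(x)
}
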