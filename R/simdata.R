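#' Random ground-truth graphs
#'
#' Draws an undirected graph on `p` nodes labeled `V1..Vp`, either an
#' Erdős–Rényi graph with a fixed edge probability (typically
#' non-decomposable) or a Barabási–Albert preferential-attachment graph
#' (a tree when `attach = 1`, hence decomposable).
#'
#' @param p Number of nodes (>= 2).
#' @param model `"erdos_renyi"` or `"barabasi"`.
#' @param density Edge probability in \[0, 1\] (Erdős–Rényi only).
#' @param attach Number of edges each new node brings (Barabási only, >= 1).
#' @param seed Integer seed; the same seed gives the same graph.
#' @return An [independence_graph].
#' @examples
#' g <- random_graph(20, "erdos_renyi", density = 0.1, seed = 1)
#' n_edges(g)
#' @export
random_graph <- function(p, model = c("erdos_renyi", "barabasi"),
                         density = NULL, attach = NULL, seed = 1L) {
  model <- match.arg(model)
  if (!is.numeric(p) || length(p) != 1L || p < 2 || p != round(p)) {
    abort("`p` must be a single integer >= 2.")
  }
  p <- as.integer(p)
  ig <- switch(model,
    erdos_renyi = {
      if (is.null(density)) abort("`density` is required for the erdos_renyi model.")
      check_scalar_number(density, "density", 0, 1)
      with_seed_(seed, igraph::sample_gnp(p, density))
    },
    barabasi = {
      if (is.null(attach)) abort("`attach` is required for the barabasi model.")
      if (!is.numeric(attach) || length(attach) != 1L || attach < 1 ||
          attach != round(attach)) {
        abort("`attach` must be a single integer >= 1.")
      }
      with_seed_(seed, igraph::sample_pa(p, m = attach, directed = FALSE))
    }
  )
  labs <- paste0("V", seq_len(p))
  el <- igraph::as_edgelist(ig, names = FALSE)
  independence_graph(labs, cbind(labs[el[, 1L]], labs[el[, 2L]]))
}

#' Sparse positive-definite precision model from a graph
#'
#' Builds the simulation ground truth: the upper-triangular adjacency pattern
#' of `graph` is filled with uniform weights on `[weight_low, weight_high]`
#' (random sign when `random_sign = TRUE`), giving an upper-triangular weight
#' matrix W; the precision matrix is the Gram matrix (I+W)'(I+W), which is
#' strictly positive definite because I+W is unit upper-triangular. The Gram
#' product introduces fill-in, so the realized graph (the nonzero pattern of
#' the precision matrix) may gain edges relative to the input graph; the
#' realized graph, not the input, is the model's truth. The partial
#' correlation matrix is the normalized precision matrix,
#' rho_ij = -omega_ij / sqrt(omega_ii * omega_jj).
#'
#' @param graph An [independence_graph] giving the sparsity pattern.
#' @param weight_low,weight_high Bounds of the uniform weight distribution
#'   (0 < low < high by default usage; any low < high is accepted).
#' @param random_sign Flip the sign of each weight independently with
#'   probability 1/2 (default `TRUE`), avoiding a systematically signed
#'   partial correlation matrix.
#' @param seed Integer seed.
#' @return A `precision_model`: list with `graph` (realized graph), `pcor`,
#'   `precision`, `partial_variances` (1/diag(precision)), and `seed`.
#' @examples
#' g <- random_graph(10, "barabasi", attach = 1, seed = 3)
#' m <- build_precision_model(g, seed = 3)
#' range(eigen(m$precision, symmetric = TRUE, only.values = TRUE)$values)
#' @export
build_precision_model <- function(graph, weight_low = 0.1, weight_high = 1,
                                  random_sign = TRUE, seed = 1L) {
  stopifnot(inherits(graph, "independence_graph"))
  if (!(weight_low < weight_high)) abort("`weight_low` must be < `weight_high`.")
  p <- n_nodes(graph)
  upper <- graph$adjacency & upper.tri(graph$adjacency)
  m <- sum(upper)
  W <- matrix(0, p, p, dimnames = dimnames(graph$adjacency))
  if (m > 0L) {
    w <- with_seed_(seed, {
      vals <- stats::runif(m, weight_low, weight_high)
      if (random_sign) vals <- vals * sample(c(-1, 1), m, replace = TRUE)
      vals
    })
    W[upper] <- w
  }
  B <- diag(p) + W
  precision <- crossprod(B)
  dimnames(precision) <- dimnames(W)
  # realized graph: fill-in can add edges; exact cancellation only on a null
  # set, guarded by a float tolerance
  realized_adj <- abs(precision) > 1e-12
  diag(realized_adj) <- FALSE
  realized <- new_independence_graph(realized_adj)
  d <- sqrt(diag(precision))
  pcor <- -precision / tcrossprod(d)
  pcor[!realized_adj] <- 0
  diag(pcor) <- 1
  structure(
    list(graph = realized, pcor = pcor, precision = precision,
         partial_variances = 1 / diag(precision), seed = as.integer(seed)),
    class = "precision_model"
  )
}

#' @export
print.precision_model <- function(x, ...) {
  cat(sprintf("<precision_model> p = %d, %d edges, seed = %d\n",
              n_nodes(x$graph), n_edges(x$graph), x$seed))
  invisible(x)
}

#' Sample a Gaussian dataset from a precision model
#'
#' Draws `n` i.i.d. rows from the mean-zero multivariate normal distribution
#' whose covariance is the inverse of `model$precision`. Sampling goes through
#' the Cholesky factor of the precision matrix (back-solve against standard
#' normals), so the covariance is never formed explicitly.
#'
#' @param model A `precision_model` from [build_precision_model()].
#' @param n Number of samples (>= 2).
#' @param seed Integer seed.
#' @return A tibble with `n` rows and one column per variable.
#' @export
sample_gaussian <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "precision_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.")
  }
  p <- n_nodes(model$graph)
  U <- tryCatch(chol(model$precision),
                error = function(e) abort("Precision matrix is not positive definite."))
  Z <- with_seed_(seed, matrix(stats::rnorm(n * p), n, p))
  # rows x solve U x = z  =>  cov(x) = (U'U)^{-1} = precision^{-1}
  X <- t(backsolve(U, t(Z)))
  colnames(X) <- model$graph$nodes
  tibble::as_tibble(X)
}

#' Is a graph decomposable (chordal)?
#'
#' Decomposable graphs admit closed-form constrained maximum-likelihood
#' covariance estimates; most biologically motivated graphs are not
#' decomposable. Uses maximum-cardinality search with a fill-in check.
#'
#' @param graph An [independence_graph].
#' @return Logical scalar.
#' @examples
#' is_decomposable(random_graph(10, "barabasi", attach = 1, seed = 1)) # tree
#' @export
is_decomposable <- function(graph) {
  stopifnot(inherits(graph, "independence_graph"))
  isTRUE(igraph::is_chordal(as_igraph(graph))$chordal)
}
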