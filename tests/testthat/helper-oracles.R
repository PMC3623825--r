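# Independent oracles used across tests. These deliberately re-derive results
# from definitions (loops, closed forms) rather than calling package code.

# Fleiss' kappa from the textbook definition: explicit per-item agreement and
# pooled category proportions, looping over items and categories.
brute_force_fleiss <- function(networks) {
  nodes <- networks[[1]]$nodes
  p <- length(nodes)
  R <- length(networks)
  items <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) items <- c(items, list(c(i, j)))
  n_mat <- matrix(0, length(items), 2) # columns: edge, non-edge
  for (it in seq_along(items)) {
    ij <- items[[it]]
    for (g in networks) {
      a <- g$adjacency[nodes[ij[1]], nodes[ij[2]]]
      n_mat[it, if (a) 1 else 2] <- n_mat[it, if (a) 1 else 2] + 1
    }
  }
  P_i <- numeric(nrow(n_mat))
  for (it in seq_len(nrow(n_mat))) {
    P_i[it] <- (sum(n_mat[it, ]^2) - R) / (R * (R - 1))
  }
  p_cat <- colSums(n_mat) / (nrow(n_mat) * R)
  P_bar <- mean(P_i)
  P_e <- sum(p_cat^2)
  if (1 - P_e < .Machine$double.eps) return(1)
  (P_bar - P_e) / (1 - P_e)
}

# Constrained Gaussian MLE on a tree by the junction-tree closed form:
# precision = sum over edges of the padded inverse 2x2 marginal minus
# (degree - 1) times the padded inverse variances.
tree_mle_precision <- function(S, graph) {
  nodes <- graph$nodes
  p <- length(nodes)
  K <- matrix(0, p, p, dimnames = list(nodes, nodes))
  deg <- rowSums(graph$adjacency)
  el <- as.matrix(graph_edges(graph))
  for (k in seq_len(nrow(el))) {
    ij <- match(el[k, ], nodes)
    K[ij, ij] <- K[ij, ij] + solve(S[ij, ij])
  }
  diag(K) <- diag(K) - (deg - 1) / diag(S)
  iso <- deg == 0
  diag(K)[iso] <- 1 / diag(S)[iso]
  K
}

# Population regression coefficients of `target` on `covariates` from a model
# covariance matrix, by the normal equations.
population_regression <- function(sigma, target, covariates) {
  drop(solve(sigma[covariates, covariates, drop = FALSE],
             sigma[covariates, target, drop = FALSE]))
}

# Brute-force acyclicity check by depth-first search.
graph_is_acyclic <- function(graph) {
  adj <- graph$adjacency
  p <- ncol(adj)
  visited <- rep(FALSE, p)
  has_cycle <- FALSE
  dfs <- function(v, parent) {
    visited[v] <<- TRUE
    for (w in which(adj[v, ])) {
      if (!visited[w]) {
        dfs(w, v)
      } else if (w != parent) {
        has_cycle <<- TRUE
      }
    }
  }
  for (v in seq_len(p)) if (!visited[v]) dfs(v, 0L)
  !has_cycle
}

# Random symmetric positive definite matrix (Gram of a Gaussian square matrix
# plus a diagonal bump).
random_spd <- function(p, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * p), p)
    crossprod(A) + diag(p) * 0.5
  })
}

# Quick simulated dataset: ER graph -> precision model -> Gaussian sample.
sim_dataset <- function(p, n, density = 0.2, seed = 1) {
  g <- random_graph(p, "erdos_renyi", density = density, seed = seed)
  m <- build_precision_model(g, seed = seed + 1)
  list(model = m, data = sample_gaussian(m, n, seed = seed + 2))
}

quiet_pacose <- function(...) suppressWarnings(pacose(...))
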