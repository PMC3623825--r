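#' Mean squared error between partial correlation matrices
#'
#' Mean of the squared differences over the p(p-1)/2 upper-triangle entries
#' (the diagonal is identically 1 and excluded, making the statistic
#' comparable across dimensions).
#'
#' @param estimate,truth Partial correlation matrices (or `pacose_fit`
#'   objects) over the same variables in the same order.
#' @return A single nonnegative number.
#' @examples
#' pcor_mse(diag(3), diag(3))
#' @export
pcor_mse <- function(estimate, truth) {
  if (inherits(estimate, "pacose_fit")) estimate <- estimate$pcor
  if (inherits(truth, "pacose_fit")) truth <- truth$pcor
  if (!is.matrix(estimate) || !is.matrix(truth) ||
      !identical(dim(estimate), dim(truth))) {
    abort("`estimate` and `truth` must be matrices of identical dimension.")
  }
  if (!is.null(colnames(estimate)) && !is.null(colnames(truth)) &&
      !identical(colnames(estimate), colnames(truth))) {
    abort("`estimate` and `truth` must have identical variable order.")
  }
  up <- upper.tri(estimate)
  mean((estimate[up] - truth[up])^2)
}

#' Confusion counts for graph recovery
#'
#' Compares an estimated graph to the true graph over all unordered node
#' pairs: an edge present in both is a true positive, only in the estimate a
#' false positive, only in the truth a false negative, in neither a true
#' negative.
#'
#' @param estimated,truth [independence_graph]s over identical node sets.
#' @return A `graph_confusion` tibble with one row and columns `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
graph_confusion <- function(estimated, truth) {
  stopifnot(inherits(estimated, "independence_graph"),
            inherits(truth, "independence_graph"))
  if (!setequal(estimated$nodes, truth$nodes)) {
    abort("Node sets of `estimated` and `truth` must agree.")
  }
  truth <- reorder_graph(truth, estimated$nodes)
  up <- upper.tri(estimated$adjacency)
  e <- estimated$adjacency[up]
  t_ <- truth$adjacency[up]
  out <- tibble::tibble(
    tp = sum(e & t_), fp = sum(e & !t_),
    fn = sum(!e & t_), tn = sum(!e & !t_)
  )
  class(out) <- c("graph_confusion", class(out))
  out
}

#' Positive predictive value and sensitivity
#'
#' PPV = TP / (TP + FP) measures how many reported edges are real (the
#' capacity to estimate sparse networks without false positives); sensitivity
#' = TP / (TP + FN) measures how many real edges are recovered. An undefined
#' ratio (0/0) is returned as `NA`, never silently 0 or 1 — e.g. the PPV of an
#' empty estimated graph is undefined and should be excluded from averages.
#'
#' @param confusion A `graph_confusion` row (or any list with `tp`, `fp`, `fn`).
#' @return A tibble with columns `ppv` and `sensitivity`.
#' @export
ppv_sensitivity <- function(confusion) {
  tp <- confusion$tp; fp <- confusion$fp; fn <- confusion$fn
  tibble::tibble(
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' Fleiss' kappa agreement between inferred networks
#'
#' Chance-corrected agreement among R >= 2 networks over the same nodes: the
#' items are the p(p-1)/2 unordered node pairs, the raters are the networks,
#' and the two categories are edge / non-edge. With P-bar the mean per-pair
#' agreement and P-bar_e the chance agreement from the pooled category
#' proportions, kappa = (P-bar - P-bar_e) / (1 - P-bar_e). The statistic is
#' always <= 1 and reaches 1 only for identical networks; by convention 1 is
#' returned when chance agreement equals 1 (identical, uniform networks).
#'
#' @param networks List of >= 2 [independence_graph]s over identical node sets.
#' @return A single number <= 1.
#' @examples
#' g1 <- independence_graph(c("a", "b", "c"), rbind(c("a", "b"), c("a", "c")))
#' g2 <- independence_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' fleiss_kappa(list(g1, g2)) # -0.5
#' @export
fleiss_kappa <- function(networks) {
  if (!is.list(networks) || length(networks) < 2L) {
    abort("`networks` must be a list of at least 2 graphs.")
  }
  nodes <- networks[[1L]]$nodes
  adj <- lapply(networks, function(g) {
    stopifnot(inherits(g, "independence_graph"))
    if (!setequal(g$nodes, nodes)) abort("All networks must share one node set.")
    reorder_graph(g, nodes)$adjacency
  })
  up <- upper.tri(adj[[1L]])
  ratings <- vapply(adj, function(a) a[up], logical(sum(up))) # pairs x raters
  ratings <- matrix(ratings, ncol = length(adj))
  R <- ncol(ratings)
  n1 <- rowSums(ratings)          # raters voting "edge" per pair
  n0 <- R - n1
  P_i <- (n1^2 + n0^2 - R) / (R * (R - 1))
  P_bar <- mean(P_i)
  p1 <- mean(n1) / R
  P_e <- p1^2 + (1 - p1)^2
  if (1 - P_e < .Machine$double.eps) return(1)
  (P_bar - P_e) / (1 - P_e)
}

#' Leave-one-group-out network stability
#'
#' Splits the samples into `groups` near-equal groups by a seeded shuffle
#' (remainder samples go one-per-leading-group), reruns the inference
#' procedure on each dataset with one group left out, and summarizes the
#' agreement of the resulting networks with Fleiss' kappa. A stable procedure
#' yields nearly identical networks under these perturbations.
#'
#' @param data Dataset, samples in rows.
#' @param infer Function taking a data subset (tibble) and returning an
#'   [independence_graph].
#' @param groups Number of groups (>= 2); the classical protocol uses 10.
#' @param seed Integer seed for the partition.
#' @return A `stability_result`: list with `kappa`, `networks` (one graph per
#'   held-out group), `group_sizes`, `group_count`, `edge_counts`.
#' @examples
#' g <- random_graph(8, "erdos_renyi", density = 0.2, seed = 9)
#' m <- build_precision_model(g, seed = 9)
#' x <- sample_gaussian(m, 80, seed = 9)
#' eng <- regression_engine("ridge_analytic")
#' res <- stability_protocol(x, function(d) {
#'   initial_graph_from_data(d, eng, threshold = 0.2)
#' }, groups = 5, seed = 1)
#' res$kappa
#' @export
stability_protocol <- function(data, infer, groups = 10L, seed = 1L) {
  X <- as_data_matrix(data)
  n <- nrow(X)
  if (!is.numeric(groups) || groups < 2) abort("`groups` must be >= 2.")
  groups <- as.integer(groups)
  if (n < 2L * groups) abort("Need at least 2 samples per group.")
  perm <- with_seed_(seed, sample.int(n))
  base <- n %/% groups
  extra <- n %% groups
  sizes <- rep(base, groups) + c(rep(1L, extra), rep(0L, groups - extra))
  assign <- rep(seq_len(groups), times = sizes)
  group_of <- integer(n)
  group_of[perm] <- assign
  networks <- vector("list", groups)
  for (g in seq_len(groups)) {
    sub <- tibble::as_tibble(X[group_of != g, , drop = FALSE])
    networks[[g]] <- tryCatch(
      infer(sub),
      error = function(e) abort(sprintf(
        "Inference failed on subset %d (group %d held out): %s",
        g, g, conditionMessage(e)))
    )
    if (!inherits(networks[[g]], "independence_graph")) {
      abort("`infer` must return an independence_graph.")
    }
  }
  structure(
    list(kappa = fleiss_kappa(networks), networks = networks,
         group_sizes = sizes, group_count = groups,
         edge_counts = vapply(networks, n_edges, 0L)),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d networks, kappa = %.3f, edges: %s\n",
              x$group_count, x$kappa, paste(x$edge_counts, collapse = " ")))
  invisible(x)
}
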