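#' Independence graphs
#'
#' An independence graph is an undirected graph over labeled variables whose
#' missing edges encode partial correlations constrained to zero (the Gaussian
#' graphical model convention). It is stored as a logical adjacency matrix
#' with the node labels as dimnames.
#'
#' @param nodes Character vector of distinct node labels (the variable names),
#'   in canonical order.
#' @param edges Edge set: a two-column data frame or matrix of node labels, or
#'   `NULL` for an edgeless graph. Self-loops are rejected; duplicate and
#'   reversed pairs are collapsed.
#'
#' @return An object of class `independence_graph`.
#' @examples
#' g <- independence_graph(c("V1", "V2", "V3"),
#'                         data.frame(from = "V1", to = "V2"))
#' n_edges(g)
#' @export
independence_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L || anyDuplicated(nodes)) {
    abort("`nodes` must be a non-empty vector of distinct labels.")
  }
  p <- length(nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) abort("`edges` must have exactly two columns.")
    if (nrow(edges) > 0L) {
      bad <- setdiff(unique(c(edges)), nodes)
      if (length(bad) > 0L) {
        abort(sprintf("Edge endpoints not in `nodes`: %s",
                      paste(bad, collapse = ", ")))
      }
      if (any(edges[, 1L] == edges[, 2L])) abort("Self-loops are not allowed.")
      i <- match(edges[, 1L], nodes)
      j <- match(edges[, 2L], nodes)
      adj[cbind(i, j)] <- TRUE
      adj[cbind(j, i)] <- TRUE
    }
  }
  new_independence_graph(adj)
}

new_independence_graph <- function(adj) {
  stopifnot(is.matrix(adj), is.logical(adj), nrow(adj) == ncol(adj))
  diag(adj) <- FALSE
  structure(list(adjacency = adj, nodes = colnames(adj)),
            class = "independence_graph")
}

#' Coerce to an independence graph
#'
#' Accepts a 0/1 (or logical) adjacency matrix with dimnames, an igraph
#' object, or a two-column edge-list data frame (node set = labels occurring
#' in it, unless `nodes` is given).
#'
#' @param x Object to coerce.
#' @param nodes Optional node labels fixing the node set and order.
#' @return An `independence_graph`.
#' @export
as_independence_graph <- function(x, nodes = NULL) {
  if (inherits(x, "independence_graph")) {
    if (!is.null(nodes)) return(reorder_graph(x, nodes))
    return(x)
  }
  if (inherits(x, "igraph")) {
    labs <- igraph::vertex_attr(x, "name") %||% paste0("V", seq_len(igraph::vcount(x)))
    el <- igraph::as_edgelist(x, names = FALSE)
    g <- independence_graph(labs,
                            cbind(labs[el[, 1L]], labs[el[, 2L]]))
    if (!is.null(nodes)) g <- reorder_graph(g, nodes)
    return(g)
  }
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) abort("Adjacency matrix must be square.")
    labs <- nodes %||% colnames(x) %||% paste0("V", seq_len(ncol(x)))
    adj <- (x != 0)
    if (!isTRUE(all.equal(adj, t(adj)))) abort("Adjacency matrix must be symmetric.")
    dimnames(adj) <- list(labs, labs)
    return(new_independence_graph(adj))
  }
  if (is.data.frame(x)) {
    labs <- nodes %||% sort(unique(c(as.character(x[[1L]]), as.character(x[[2L]]))))
    return(independence_graph(labs, x[, 1:2]))
  }
  abort("Cannot coerce this object to an independence graph.")
}

reorder_graph <- function(graph, nodes) {
  if (!setequal(nodes, graph$nodes)) {
    abort("Node sets differ; cannot reorder graph.")
  }
  new_independence_graph(graph$adjacency[nodes, nodes, drop = FALSE])
}

#' @export
print.independence_graph <- function(x, ...) {
  cat(sprintf("<independence_graph> %d nodes, %d edges\n",
              n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Graph accessors
#'
#' @param graph An `independence_graph`.
#' @return `n_nodes()`/`n_edges()` return integers; `graph_edges()` a tibble
#'   with columns `from` and `to` (unordered pairs in canonical order);
#'   `graph_neighbors()` a character vector of adjacent node labels.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) sum(graph$adjacency[upper.tri(graph$adjacency)])

#' @rdname n_nodes
#' @export
graph_edges <- function(graph) {
  idx <- which(graph$adjacency & upper.tri(graph$adjacency), arr.ind = TRUE)
  tibble::tibble(from = graph$nodes[idx[, 1L]], to = graph$nodes[idx[, 2L]]) |>
    dplyr::arrange(match(.data$from, graph$nodes), match(.data$to, graph$nodes))
}

#' @rdname n_nodes
#' @param node A node label.
#' @export
graph_neighbors <- function(graph, node) {
  if (!node %in% graph$nodes) abort(sprintf("Unknown node `%s`.", node))
  graph$nodes[graph$adjacency[node, ]]
}

#' Empty and complete graphs on a node set
#'
#' @param nodes Character vector of node labels.
#' @return An `independence_graph` with no edges (`empty_graph`) or all
#'   p(p-1)/2 edges (`complete_graph`).
#' @export
empty_graph <- function(nodes) independence_graph(nodes)

#' @rdname empty_graph
#' @export
complete_graph <- function(nodes) {
  g <- independence_graph(nodes)
  g$adjacency[] <- TRUE
  diag(g$adjacency) <- FALSE
  g
}

#' Test two graphs for equality
#'
#' Equality means identical node sets (order-insensitive) and identical edge
#' sets.
#'
#' @param a,b `independence_graph` objects.
#' @return Logical scalar.
#' @export
graph_equal <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  b <- reorder_graph(b, a$nodes)
  identical(a$adjacency, b$adjacency)
}

# Canonical string key for visited-set bookkeeping.
graph_key <- function(graph) {
  paste(which(graph$adjacency[upper.tri(graph$adjacency)]), collapse = ",")
}

#' Convert an independence graph to an igraph object
#'
#' @param graph An `independence_graph`.
#' @return An undirected `igraph` graph with vertex names.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency * 1, mode = "undirected")
}
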