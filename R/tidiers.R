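#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a graph-constrained partial correlation fit
#'
#' @param x A `pacose_fit`.
#' @param keep_zeros Include constrained (non-edge) pairs as zero rows
#'   (default `FALSE`: one row per graph edge).
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `pcor`.
#' @export
tidy.pacose_fit <- function(x, keep_zeros = FALSE, ...) {
  idx <- upper_pairs(n_nodes(x$graph))
  out <- tibble::tibble(
    from = x$graph$nodes[idx[, 1L]],
    to = x$graph$nodes[idx[, 2L]],
    pcor = x$pcor[idx],
    edge = x$graph$adjacency[idx]
  )
  if (!keep_zeros) out <- dplyr::filter(out, .data$edge)
  dplyr::select(out, -"edge")
}

#' @rdname tidy.pacose_fit
#' @export
glance.pacose_fit <- function(x, ...) {
  tibble::tibble(
    p = n_nodes(x$graph), n = x$n, n_edges = n_edges(x$graph),
    engine = x$engine$name, n_discordant = nrow(x$discordant),
    n_clipped = x$clipped
  )
}

#' Tidy an iterative inference trace
#'
#' One row per iteration with the edge count after thresholding and whether
#' the graph changed relative to the previous iteration.
#'
#' @param x An `ipacose_fit`.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `n_edges`, `n_discordant`,
#'   `changed`.
#' @export
tidy.ipacose_fit <- function(x, ...) {
  counts <- vapply(x$iterations, `[[`, 0L, "n_edges")
  disc <- vapply(x$iterations, `[[`, 0L, "n_discordant")
  tibble::tibble(
    iteration = seq_along(counts),
    n_edges = counts,
    n_discordant = disc,
    changed = c(TRUE, diff(counts) != 0 |
                  !mapply(function(a, b) graph_equal(a$graph, b$graph),
                          x$iterations[-length(x$iterations)],
                          x$iterations[-1L]))
  )
}

#' @rdname tidy.ipacose_fit
#' @export
glance.ipacose_fit <- function(x, ...) {
  tibble::tibble(
    iterations = length(x$iterations), stop_reason = x$stop_reason,
    threshold = x$threshold, final_edges = n_edges(x$final_graph),
    engine = x$engine$name
  )
}

#' Heatmap of an estimated partial correlation matrix
#'
#' @param object A `pacose_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pacose_fit <- function(object, ...) {
  nodes <- object$graph$nodes
  df <- tidyr::expand_grid(from = nodes, to = nodes) |>
    dplyr::mutate(pcor = as.vector(t(object$pcor)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$to, nodes),
    y = factor(.data$from, rev(nodes)), fill = .data$pcor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial\ncorrelation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Edge-count trajectory of an iterative inference run
#'
#' @param object An `ipacose_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipacose_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$n_edges)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "edges after thresholding",
                  subtitle = sprintf("threshold = %g, stop: %s",
                                     object$threshold, object$stop_reason)) +
    ggplot2::theme_minimal()
}

#' Threshold sweep of graph-recovery performance
#'
#' Plots PPV and sensitivity per threshold and method from a tidy experiment
#' table as produced by [run_experiment()] (scenario `"graph"`).
#'
#' @param results Tibble with columns `threshold`, `method`, `ppv`,
#'   `sensitivity`.
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(results) {
  df <- results |>
    tidyr::pivot_longer(c("ppv", "sensitivity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$threshold, .data$method, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "threshold", y = NULL) +
    ggplot2::theme_minimal()
}
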