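# Tab-separated input/output for datasets, matrices and graphs.

#' Read and write datasets and labeled matrices as TSV
#'
#' Datasets are TSV with a header row of variable names, rows = samples.
#' Square matrices (partial correlation, precision, adjacency) are TSV with
#' both row and column labels.
#'
#' @param path File path.
#' @return `read_data_tsv()` a tibble; `read_matrix_tsv()` a labeled matrix.
#' @export
read_data_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_data_tsv
#' @param data Data frame or matrix to write.
#' @export
write_data_tsv <- function(data, path) {
  readr::write_tsv(tibble::as_tibble(as_data_matrix(data)), path)
  invisible(path)
}

#' @rdname read_data_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname read_data_tsv
#' @param m Labeled square matrix to write.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m) %||% colnames(m), m,
                   check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}

#' Read and write independence graphs as TSV
#'
#' Two formats are accepted and auto-detected: a two-column edge list with
#' header `source`/`target`, or a labeled 0/1 adjacency matrix (first column =
#' row labels). Writing uses the edge-list format by default.
#'
#' @param path File path.
#' @param nodes Optional node labels (required to recover isolated nodes from
#'   an edge list).
#' @return An [independence_graph].
#' @export
read_graph_tsv <- function(path, nodes = NULL) {
  header <- strsplit(readr::read_lines(path, n_max = 1L), "\t")[[1L]]
  if (length(header) == 2L) {
    el <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    labs <- nodes %||% sort(unique(c(el[[1L]], el[[2L]])))
    return(independence_graph(labs, as.matrix(el)))
  }
  as_independence_graph(read_matrix_tsv(path), nodes = nodes)
}

#' @rdname read_graph_tsv
#' @param graph An [independence_graph].
#' @param format `"edges"` (two-column `source`/`target` list) or
#'   `"adjacency"` (labeled 0/1 matrix).
#' @export
write_graph_tsv <- function(graph, path, format = c("edges", "adjacency")) {
  format <- match.arg(format)
  if (format == "edges") {
    el <- graph_edges(graph)
    names(el) <- c("source", "target")
    readr::write_tsv(el, path)
  } else {
    write_matrix_tsv(graph$adjacency * 1L, path)
  }
  invisible(path)
}
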