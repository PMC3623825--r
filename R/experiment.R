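#' Configuration for a simulation experiment
#'
#' Bundles the generator settings, the engine(s) and the evaluation protocol
#' for [run_experiment()]. Three scenarios cover the package's simulation
#' studies:
#' \describe{
#'   \item{`"mse"`}{accuracy of the partial correlation matrix given the true
#'     graph: graph-constrained fits per engine vs. the unconstrained
#'     shrinkage baseline, plus IPF covariance selection when the graph is
#'     decomposable and n > p; metric = matrix MSE against the true matrix.}
#'   \item{`"graph"`}{graph recovery: the iterative procedure vs. its
#'     non-iterative counterpart (threshold the complete-graph fit), swept
#'     over thresholds; metrics = PPV and sensitivity against the true graph.}
#'   \item{`"stability"`}{leave-one-group-out stability of both procedures;
#'     metric = Fleiss' kappa.}
#' }
#'
#' @param scenario One of `"mse"`, `"graph"`, `"stability"`.
#' @param p,n Number of variables / samples per replicate.
#' @param graph_model,density,attach Passed to [random_graph()].
#' @param weight_low,weight_high Passed to [build_precision_model()].
#' @param engines Character vector of engine names (see
#'   [regression_engine()]); scenarios `"graph"` and `"stability"` use the
#'   first entry.
#' @param cv_folds Cross-validation folds for the engines.
#' @param thresholds Thresholds swept in `"graph"`, and the single working
#'   threshold (first entry) in `"stability"`.
#' @param groups Number of exclusion groups in `"stability"`.
#' @param replicates Number of independent simulated datasets.
#' @param seed Base seed; every replicate derives its own seeds from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scenario = c("mse", "graph", "stability"),
                              p = 50L, n = 100L,
                              graph_model = c("erdos_renyi", "barabasi"),
                              density = 0.1, attach = 1L,
                              weight_low = 0.1, weight_high = 1,
                              engines = "ridge_cv", cv_folds = 10L,
                              thresholds = c(0.05, 0.1, 0.15, 0.2),
                              groups = 10L, replicates = 10L, seed = 1L) {
  scenario <- match.arg(scenario)
  graph_model <- match.arg(graph_model)
  stopifnot(replicates >= 1, all(thresholds > 0 & thresholds < 1))
  structure(
    list(scenario = scenario, p = as.integer(p), n = as.integer(n),
         graph_model = graph_model, density = density,
         attach = as.integer(attach), weight_low = weight_low,
         weight_high = weight_high, engines = engines,
         cv_folds = as.integer(cv_folds), thresholds = thresholds,
         groups = as.integer(groups), replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run a simulation experiment
#'
#' Simulates `replicates` datasets from the generator in `config`, runs the
#' estimators the scenario asks for and scores them. Deterministic: rerunning
#' with the same config reproduces the table. Failures in a single replicate
#' are recorded (`error` column) and the run continues.
#'
#' @param config An [experiment_config()].
#' @return A tidy tibble, one row per replicate x method (x threshold for the
#'   `"graph"` scenario), with the config attached as attribute `"config"`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- purrr::map(seq_len(config$replicates), function(r) {
    tryCatch(
      run_replicate(config, r),
      error = function(e) tibble::tibble(replicate = r,
                                         method = NA_character_,
                                         error = conditionMessage(e))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!"error" %in% names(out)) out$error <- NA_character_
  attr(out, "config") <- config
  out
}

replicate_seed <- function(config, r) {
  (config$seed + 7919L * r) %% 2000000000L
}

simulate_replicate <- function(config, r) {
  s <- replicate_seed(config, r)
  graph0 <- random_graph(config$p, config$graph_model,
                         density = config$density, attach = config$attach,
                         seed = s)
  model <- build_precision_model(graph0, config$weight_low,
                                 config$weight_high, seed = s + 1L)
  data <- sample_gaussian(model, config$n, seed = s + 2L)
  list(model = model, data = data, seed = s)
}

run_replicate <- function(config, r) {
  sim <- simulate_replicate(config, r)
  switch(config$scenario,
    mse = replicate_mse(config, r, sim),
    graph = replicate_graph(config, r, sim),
    stability = replicate_stability(config, r, sim)
  )
}

replicate_mse <- function(config, r, sim) {
  truth <- sim$model$pcor
  rows <- purrr::map(config$engines, function(eng_name) {
    eng <- regression_engine(eng_name, cv_folds = config$cv_folds,
                             seed = sim$seed)
    fit <- run_pacose_quietly(sim$data, sim$model$graph, eng)
    tibble::tibble(replicate = r, method = paste0("constrained_", eng_name),
                   mse = pcor_mse(fit$pcor, truth), seed = sim$seed)
  })
  rows <- c(rows, list(tibble::tibble(
    replicate = r, method = "shrinkage",
    mse = pcor_mse(shrinkage_pcor(sim$data), truth), seed = sim$seed
  )))
  if (config$n > config$p && is_decomposable(sim$model$graph)) {
    S <- stats::cov(as_data_matrix(sim$data))
    ipf <- ipf_covariance_selection(S, sim$model$graph)
    rows <- c(rows, list(tibble::tibble(
      replicate = r, method = "ipf",
      mse = pcor_mse(precision_to_pcor(ipf$precision), truth), seed = sim$seed
    )))
  }
  dplyr::bind_rows(rows)
}

replicate_graph <- function(config, r, sim) {
  eng <- regression_engine(config$engines[[1L]], cv_folds = config$cv_folds,
                           seed = sim$seed)
  # complete-graph fit computed once; its thresholdings are the non-iterative
  # baselines for every threshold
  base_fit <- run_pacose_quietly(sim$data, complete_graph(sim$model$graph$nodes),
                                 eng)
  purrr::map_dfr(config$thresholds, function(t) {
    base_graph <- threshold_graph(base_fit$pcor, t)
    it <- ipacose(sim$data, base_graph, t, eng)
    dplyr::bind_rows(
      dplyr::bind_cols(
        tibble::tibble(replicate = r, threshold = t, method = "non_iterative",
                       n_edges = n_edges(base_graph)),
        ppv_sensitivity(graph_confusion(base_graph, sim$model$graph))
      ),
      dplyr::bind_cols(
        tibble::tibble(replicate = r, threshold = t, method = "iterative",
                       n_edges = n_edges(it$final_graph)),
        ppv_sensitivity(graph_confusion(it$final_graph, sim$model$graph))
      )
    )
  }) |>
    dplyr::mutate(seed = sim$seed)
}

replicate_stability <- function(config, r, sim) {
  t <- config$thresholds[[1L]]
  eng <- regression_engine(config$engines[[1L]], cv_folds = config$cv_folds,
                           seed = sim$seed)
  infer_pair <- function(d) {
    base <- initial_graph_from_data(d, eng, t)
    list(base = base,
         iter = ipacose(d, base, t, eng)$final_graph)
  }
  # one pass per subset serves both methods: the non-iterative network is the
  # iterative run's starting graph
  cache <- new.env(parent = emptyenv())
  infer_cached <- function(d, which) {
    key <- digest_rows(d)
    if (is.null(cache[[key]])) cache[[key]] <- infer_pair(d)
    cache[[key]][[which]]
  }
  res_base <- stability_protocol(sim$data, function(d) infer_cached(d, "base"),
                                 groups = config$groups, seed = sim$seed)
  res_iter <- stability_protocol(sim$data, function(d) infer_cached(d, "iter"),
                                 groups = config$groups, seed = sim$seed)
  tibble::tibble(
    replicate = r, method = c("non_iterative", "iterative"),
    kappa = c(res_base$kappa, res_iter$kappa),
    threshold = t, seed = sim$seed
  )
}

# cheap deterministic key for a data subset (used only for within-replicate
# caching, where subsets are distinguished by their row sums)
digest_rows <- function(d) {
  paste(format(sum(as.matrix(d)), digits = 15),
        nrow(d), format(sum(as.matrix(d)^2), digits = 15), sep = "|")
}
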