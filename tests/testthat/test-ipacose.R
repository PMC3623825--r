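test_that("thresholding uses strict inequality and is monotone", {
  expect_equal(n_edges(threshold_graph(diag(4), 0.3)), 0L)

  pc <- diag(3)
  pc[1, 2] <- pc[2, 1] <- 0.6
  pc[1, 3] <- pc[3, 1] <- 0.4
  pc[2, 3] <- pc[3, 2] <- 0.5
  dimnames(pc) <- list(paste0("V", 1:3), paste0("V", 1:3))
  expect_equal(n_edges(threshold_graph(pc, 0.5)), 1L) # 0.5 itself excluded

  for (s in 1:5) {
    m <- build_precision_model(random_graph(10, "erdos_renyi", density = 0.3,
                                            seed = s), seed = s)
    lo <- threshold_graph(m$pcor, 0.3)
    hi <- threshold_graph(m$pcor, 0.4)
    expect_true(all(lo$adjacency[hi$adjacency])) # edge nesting
  }
  expect_error(threshold_graph(diag(3), 1.5), "threshold")
})

test_that("an empty starting graph is a fixed point reached in at most two iterations", {
  sim <- sim_dataset(6, 100, density = 0.2, seed = 200)
  fit <- ipacose(sim$data, empty_graph(colnames(sim$data)), 0.2,
                 regression_engine("ols"))
  expect_equal(fit$stop_reason, "converged")
  expect_lte(length(fit$iterations), 2L)
  expect_equal(n_edges(fit$final_graph), 0L)
})

test_that("traces are internally consistent and reproducible", {
  sim <- sim_dataset(12, 100, density = 0.15, seed = 210)
  eng <- regression_engine("ridge_cv", seed = 7)
  init <- initial_graph_from_data(sim$data, eng, 0.1)
  f1 <- ipacose(sim$data, init, 0.1, eng)
  f2 <- ipacose(sim$data, init, 0.1, eng)
  expect_identical(lapply(f1$iterations, `[[`, "pcor"),
                   lapply(f2$iterations, `[[`, "pcor"))
  expect_identical(f1$stop_reason, f2$stop_reason)

  # each iteration's graph is the thresholding of that iteration's pcor, and
  # each pcor obeys the previous graph's zero constraints exactly
  prev <- init
  for (it in f1$iterations) {
    expect_true(graph_equal(it$graph, threshold_graph(it$pcor, 0.1)))
    non_edge <- !prev$adjacency & upper.tri(prev$adjacency)
    expect_identical(unname(it$pcor[non_edge]), rep(0, sum(non_edge)))
    prev <- it$graph
  }
  if (f1$stop_reason == "converged") {
    k <- length(f1$iterations)
    expect_true(graph_equal(f1$iterations[[k]]$graph,
                            f1$iterations[[k - 1]]$graph))
  }
})

test_that("max_iter is a hard cap with the matching stop reason", {
  sim <- sim_dataset(10, 80, density = 0.2, seed = 220)
  fit <- ipacose(sim$data, complete_graph(colnames(sim$data)), 0.05,
                 regression_engine("ridge_analytic"), max_iter = 1)
  expect_equal(fit$stop_reason, "max_iter")
  expect_length(fit$iterations, 1L)
})

test_that("re-estimation mostly prunes: edge counts are non-increasing in >= 90% of runs", {
  eng <- regression_engine("ridge_analytic")
  monotone <- vapply(1:20, function(s) {
    g <- random_graph(20, "erdos_renyi", density = 0.1, seed = 300 + s)
    m <- build_precision_model(g, seed = 300 + s)
    x <- sample_gaussian(m, 100, seed = 300 + s)
    init <- initial_graph_from_data(x, eng, 0.1)
    fit <- ipacose(x, init, 0.1, eng)
    counts <- c(n_edges(init), vapply(fit$iterations, `[[`, 0L, "n_edges"))
    all(diff(counts) <= 0)
  }, logical(1))
  expect_gte(mean(monotone), 0.9)
})

test_that("initial graph estimation reduces to thresholded classical pcor for ols", {
  sim <- sim_dataset(8, 1000, density = 0.25, seed = 230)
  got <- initial_graph_from_data(sim$data, regression_engine("ols"), 0.1)
  oracle <- threshold_graph(precision_to_pcor(solve(cov(as.matrix(sim$data)))),
                            0.1)
  expect_true(graph_equal(got, oracle))
  # extreme thresholds
  expect_equal(n_edges(initial_graph_from_data(sim$data,
                                               regression_engine("ols"),
                                               0.999)), 0L)
  expect_equal(n_edges(initial_graph_from_data(sim$data,
                                               regression_engine("ols"),
                                               1e-12)),
               choose(8, 2))
})

test_that("tidiers summarize traces", {
  sim <- sim_dataset(10, 100, density = 0.15, seed = 240)
  eng <- regression_engine("ridge_analytic")
  fit <- ipacose(sim$data, initial_graph_from_data(sim$data, eng, 0.1), 0.1, eng)
  td <- tidy(fit)
  expect_named(td, c("iteration", "n_edges", "n_discordant", "changed"))
  expect_equal(nrow(td), length(fit$iterations))
  gl <- glance(fit)
  expect_equal(gl$final_edges, n_edges(fit$final_graph))
  expect_s3_class(autoplot(fit), "ggplot")
})
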