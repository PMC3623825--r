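test_that("neighbor regression restricts to graph neighbors", {
  sim <- sim_dataset(6, 100, density = 0.4, seed = 21)
  g <- sim$model$graph
  target <- g$nodes[[1]]
  fit <- fit_neighbor_regression(sim$data, target, g)
  expect_identical(fit$neighbor_labels, graph_neighbors(g, target))
  expect_named(fit$coefficients, fit$neighbor_labels)

  isolated <- fit_neighbor_regression(sim$data, target, empty_graph(g$nodes))
  expect_length(isolated$coefficients, 0L)
})

test_that("neighbor regression matches the population coefficients on a chain", {
  # V1 - V2 - V3 chain; oracle = normal equations on the model covariance
  g <- independence_graph(paste0("V", 1:3),
                          rbind(c("V1", "V2"), c("V2", "V3")))
  m <- build_precision_model(g, seed = 31)
  sigma <- solve(m$precision)
  x <- sample_gaussian(m, 50000, seed = 31)
  fit <- fit_neighbor_regression(x, "V2", m$graph, regression_engine("ols"))
  oracle <- population_regression(sigma, 2, match(fit$neighbor_labels, g$nodes))
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 0.02)
})

test_that("complete-graph ols coefficients equal the scaled inverse covariance rows", {
  sim <- sim_dataset(8, 2000, density = 0.3, seed = 41)
  X <- as.matrix(sim$data)
  omega_hat <- solve(cov(X))
  g <- complete_graph(colnames(X))
  for (i in c(1L, 5L)) {
    fit <- fit_neighbor_regression(sim$data, colnames(X)[i], g,
                                   regression_engine("ols"))
    oracle <- -omega_hat[i, -i] / omega_hat[i, i]
    expect_equal(fit$coefficients, oracle[fit$neighbor_labels],
                 tolerance = 1e-8)
  }
})

test_that("the empty graph yields the identity matrix", {
  sim <- sim_dataset(5, 50, seed = 51)
  fit <- pacose(sim$data, empty_graph(colnames(sim$data)))
  expect_identical(unname(fit$pcor), diag(5))
})

test_that("complete graph with ols reproduces the classical unconstrained estimator", {
  sim <- sim_dataset(10, 400, density = 0.2, seed = 61)
  fit <- pacose(sim$data, complete_graph(colnames(sim$data)),
                regression_engine("ols"))
  oracle <- precision_to_pcor(solve(cov(as.matrix(sim$data))))
  expect_lt(max(abs(fit$pcor - oracle)), 1e-8)
})

test_that("non-edge entries are literal zeros and invariants hold for every engine", {
  sim <- sim_dataset(8, 60, density = 0.25, seed = 71)
  g <- sim$model$graph
  non_edge <- !g$adjacency & upper.tri(g$adjacency)
  for (name in c("ols", "ridge_cv", "ridge_analytic", "pls", "lasso", "adalasso")) {
    fit <- quiet_pacose(sim$data, g, regression_engine(name, seed = 5))
    expect_identical(unname(fit$pcor[non_edge]),
                     rep(0, sum(non_edge)), info = name)
    expect_true(isSymmetric(fit$pcor), info = name)
    expect_identical(unname(diag(fit$pcor)), rep(1, 8), info = name)
    expect_lte(max(abs(fit$pcor)), 1)
  }
})

test_that("graph node order is canonicalized to the data column order", {
  sim <- sim_dataset(6, 80, density = 0.3, seed = 81)
  g <- sim$model$graph
  shuffled <- pcorsel:::reorder_graph(g, rev(g$nodes))
  f1 <- pacose(sim$data, g, regression_engine("ols"))
  f2 <- pacose(sim$data, shuffled, regression_engine("ols"))
  expect_identical(f1$pcor, f2$pcor)
})

test_that("sign-discordant coefficient pairs are zeroed and reported", {
  B <- matrix(0, 3, 3, dimnames = list(paste0("V", 1:3), paste0("V", 1:3)))
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- TRUE
  adj[1, 3] <- adj[3, 1] <- TRUE
  B[1, 2] <- 0.5; B[2, 1] <- -0.3   # discordant
  B[1, 3] <- 0.4; B[3, 1] <- 0.9    # concordant
  comb <- pcorsel:::combine_beta_matrix(B, adj)
  expect_identical(comb$pcor[1, 2], 0)
  expect_equal(comb$pcor[1, 3], sqrt(0.4 * 0.9))
  expect_equal(nrow(comb$discordant), 1L)

  # clipping: concordant product above 1
  B[1, 2] <- 1.5; B[2, 1] <- 1.5
  comb2 <- pcorsel:::combine_beta_matrix(B, adj)
  expect_identical(comb2$pcor[1, 2], 1)
  expect_equal(comb2$clipped, 1L)
})

test_that("the estimator is consistent: error shrinks with tenfold more samples", {
  errs <- sapply(1:5, function(s) {
    g <- random_graph(10, "erdos_renyi", density = 0.2, seed = s + 100)
    m <- build_precision_model(g, seed = s + 100)
    sapply(c(300, 3000), function(n) {
      fit <- pacose(sample_gaussian(m, n, seed = s), m$graph,
                    regression_engine("ols"))
      max(abs(fit$pcor - m$pcor))
    })
  })
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})

test_that("precision-scale reconstruction inverts the normalization", {
  expect_identical(pcor_to_precision_scale(diag(3), rep(1, 3)), diag(3))
  m <- build_precision_model(random_graph(12, "erdos_renyi", density = 0.2,
                                          seed = 91), seed = 91)
  rebuilt <- pcor_to_precision_scale(m$pcor, m$partial_variances)
  expect_lt(max(abs(rebuilt - m$precision)), 1e-10)
  # round trip in the other direction
  expect_equal(precision_to_pcor(rebuilt), m$pcor, tolerance = 1e-12)
  expect_error(pcor_to_precision_scale(m$pcor, rep(-1, 12)), "positive")
})

test_that("input validation names the offender", {
  sim <- sim_dataset(5, 40, seed = 101)
  bad <- as.matrix(sim$data)
  bad[, 2] <- 1
  expect_error(pacose(bad, sim$model$graph), "Zero-variance.*V2")
  expect_error(pacose(sim$data, empty_graph(paste0("W", 1:5))), "agree")
  # saturated ols propagates with the node named
  small <- sim_dataset(8, 6, density = 0.9, seed = 111)
  expect_error(pacose(small$data, complete_graph(colnames(small$data)),
                      regression_engine("ols")),
               "node")
})
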