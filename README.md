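# pcorsel

Graph-constrained partial correlation estimation and iterative Gaussian
graphical model (GGM) inference.

## The problem

In a Gaussian graphical model, the partial correlation between variables
$i$ and $j$ given all others is obtained from the precision matrix
$\Omega = \Sigma^{-1}$ as

$$\rho_{ij} = -\frac{\omega_{ij}}{\sqrt{\omega_{ii}\,\omega_{jj}}},$$

and $\rho_{ij} = 0$ exactly when $i$ and $j$ are conditionally independent.
Biological applications usually come with two complications: prior knowledge
in the form of an *independence graph* (missing edges = partial correlations
known to be zero), and far fewer samples than variables, so the sample
covariance cannot be inverted. Most covariance-selection methods that exploit
a known graph additionally require it to be decomposable — which real
biological graphs rarely are.

`pcorsel` estimates the partial correlation matrix directly under an
arbitrary (decomposable or not) graph constraint, using the regression
characterization of partial correlations: each variable is regressed on its
graph neighbors only, and for every edge

$$\hat\rho_{ij} = \mathrm{sign}(\hat\beta_{ij})\,
  \sqrt{\hat\beta_{ij}\,\hat\beta_{ji}},$$

while non-edges are exact zeros. The per-node regressions use pluggable
engines — least squares, cross-validated or analytic ridge, PLS, lasso,
adaptive lasso — so the estimator works when a node has more neighbors than
there are samples.

Stacking this estimator into a loop gives an iterative graph-inference
procedure: estimate the matrix, keep edges with $|\hat\rho_{ij}|$ above a
threshold, re-estimate under the new graph, repeat until the graph is stable.
Re-estimated coefficients of spurious edges tend to drop below the threshold,
so iteration prunes false positives (higher positive predictive value) at a
small sensitivity cost, and makes the inferred network more stable under
data perturbations.

The package also ships the supporting cast: a sparse positive-definite
simulation generator (Erdős–Rényi / preferential-attachment graphs, Gram
construction $(I+W)^\top(I+W)$), an iterative-proportional-fitting
covariance-selection baseline, an identity-target shrinkage baseline, and
evaluation statistics (matrix MSE, PPV/sensitivity, leave-one-group-out
Fleiss' $\kappa$ stability).

## Worked example

```r
library(pcorsel)

g <- random_graph(20, "erdos_renyi", density = 0.1, seed = 42)
model <- build_precision_model(g, seed = 42)   # ground-truth pcor + precision
x <- sample_gaussian(model, n = 100, seed = 42)
model
#> <precision_model> p = 20, 43 edges, seed = 42
```

Estimate the matrix under the true graph and score it:

```r
fit <- pacose(x, model$graph, regression_engine("ols"))
fit
#> <pacose_fit> p = 20, n = 100, engine = ols, 43 constrained edges
head(tidy(fit), 4)
#> # A tibble: 4 × 3
#>   from  to     pcor
#>   <chr> <chr> <dbl>
#> 1 V1    V4    0.646
#> 2 V1    V5    0.658
#> 3 V1    V17   0.238
#> 4 V1    V18   0.178
pcor_mse(fit$pcor, model$pcor)
#> [1] 0.001061705
```

Infer the graph from scratch, iteratively:

```r
eng <- regression_engine("ridge_analytic")
init <- initial_graph_from_data(x, eng, threshold = 0.1)  # non-iterative baseline
fit_it <- ipacose(x, init, threshold = 0.1, engine = eng)
tidy(fit_it)
#> # A tibble: 3 × 4
#>   iteration n_edges n_discordant changed
#>       <int>   <int>        <int> <lgl>
#> 1         1      37            0 TRUE
#> 2         2      35            0 TRUE
#> 3         3      35            0 FALSE

ppv_sensitivity(graph_confusion(fit_it$final_graph, model$graph))
#> # A tibble: 1 × 2
#>     ppv sensitivity
#> 1 0.886       0.721
ppv_sensitivity(graph_confusion(init, model$graph))
#> # A tibble: 1 × 2
#>     ppv sensitivity
#> 1  0.75       0.767
```

Iteration converged in 3 steps and raised the PPV from 0.75 to 0.886 (fewer
false edges) while sensitivity slipped from 0.767 to 0.721 — the trade the
procedure is designed to make. `autoplot()` methods draw the pcor heatmap
and the edge-count trajectory; `run_experiment()` wraps the replicated
simulation designs (`"mse"`, `"graph"`, `"stability"`).

A command-line interface covering simulation, estimation, iterative
inference, covariance selection, evaluation and the stability protocol is in
`inst/cli/pcorsel.R`:

```sh
Rscript inst/cli/pcorsel.R simulate --p 50 --n 100 --graph-model er --density 0.1 --seed 1 --out sim/
Rscript inst/cli/pcorsel.R pacose --data sim/data.tsv --graph sim/graph.tsv --engine ridge_cv --out pcor.tsv
```

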