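# priorpc

Gene regulatory network (GRN) skeleton reconstruction from steady-state
expression data, with optional **soft prior knowledge**.

## The problem

Inferring which genes interact from expression data is hard: the number of
genes far exceeds the number of samples, and measurements are noisy. The PC
algorithm — a popular constraint-based Bayesian-network method — builds the
undirected skeleton by deleting the edge between genes `X_i` and `X_j`
whenever a conditioning set `Y` is found with `X_i ⊥ X_j | Y`. Assuming
multivariate-Gaussian expression, each conditional-independence (CI) test
checks zero partial correlation via Fisher's z-transform: the edge is kept
unless

    |z(X_i, X_j | Y)| * sqrt(n - |Y| - 3)  <=  t,
    z(r) = ½ log((1+r)/(1-r)),

with threshold `t = 0.1` and conditioning sets capped at `|Y| <= 5` by
default. With few samples these tests err, and then the output depends on
the order in which variables are processed.

**PriorPC** turns that weakness into a feature. Given a prior belief matrix
`B` with `b_ij ∈ [0,1]` (0.5 = no information), it scores every gene pair
with a confidence score

    s_ij = α · b_ij + (1 − α) · d_ij,

where `d_ij` is a CLR-style data score measuring how far the pair's absolute
correlation `C_ij` deviates from both genes' correlation backgrounds:

    d_ij = |C_ij − μ_i| / (1 − μ_i)  ×  |C_ij − μ_j| / (1 − μ_j),

with `μ_i` the mean absolute correlation of gene i to all other genes. The
algorithm then (1) discards all but the top `N_E ≈ 3·|E|` pairs by `s`
(replacing the order-0 tests), (2) splits the survivors into
strong/average/weak thirds, and (3) runs CI tests of order 1..5 on the weak
candidates first and the strong candidates last, so that poorly supported
edges are removed before they can corrupt the neighbourhoods used to test
well-supported ones. A posteriori edge confidence comes from bootstrap
consensus: the algorithm is rerun on `K = 20` resampled datasets and edges
are ranked by their frequency of appearance, which is what AUROC/AUPRC are
computed on against a gold standard.

The package also provides the **PC-lite** baseline (seeds the graph with the
top-`N_E` marginal-correlation pairs instead of using priors), an exact
**d-separation oracle** for ground-truth experiments, synthetic prior
generators (true / noise-corrupted / flipped), and a linear-Gaussian
benchmark simulator at DREAM4 scale (100 genes, 176 interactions, 100
samples).

## Worked example

```r
library(priorpc)

# a seeded synthetic benchmark: sparse random DAG + linear-Gaussian samples
spec <- benchmark_spec(n_nodes = 100, n_edges = 176, n_samples = 100, seed = 7)
bm <- make_benchmark(spec)
bm$data
#> <expression_dataset> 100 genes x 100 samples

# priors: half of all gene pairs get an informative belief drawn from the
# correct side of 0.5, the rest stay non-informative
B <- true_priors(bm$gold, coverage = 0.5, seed = 8)

cfg <- run_config(algorithm = "priorpc", alpha = 0.5,
                  expected_edges = 176, K = 20, seed = 9)
res <- run_experiment(bm$data, cfg, prior = B, gold = bm$gold)
head(res$ranking, 5)
#>   from   to score
#> 1 G001 G029    20
#> 2 G001 G067    20
#> 3 G001 G098    20
#> 4 G002 G017    20
#> 5 G003 G011    20
```

The score is the number of bootstrap networks (out of `K = 20`) containing
the edge; these top edges survived every resample. Against the known gold
standard, evaluation is restricted to gene pairs whose endpoints have at
least one gold interaction:

```r
res$metrics
#> AUROC = 0.970, AUPRC = 0.892

# the prior-free baseline on the same data, same bootstrap seed:
lite <- run_experiment(bm$data,
  run_config(algorithm = "pc-lite", expected_edges = 176, K = 20, seed = 9),
  gold = bm$gold)
lite$metrics
#> AUROC = 0.947, AUPRC = 0.801
```

Half-coverage priors at `α = 0.5` lift AUPRC from 0.80 to 0.89 here; the
gain grows with prior coverage and with `α` when priors are reliable.

A thin command-line front end with `simulate`, `make-priors`, `run` and
`evaluate` subcommands is installed at
`system.file("cli", "priorpc-cli.R", package = "priorpc")`; outputs are
tab-separated edge lists directly loadable in Cytoscape.

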