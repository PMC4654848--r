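#' Benchmark specification
#'
#' Parameters of a synthetic benchmark emulating a DREAM4-scale inference
#' problem: a sparse random DAG over ~100 genes with ~176 interactions and
#' ~100 steady-state samples of multivariate-Gaussian expression. Structural
#' coefficients are bounded away from zero so that true edges carry
#' detectable signal at this sample size.
#'
#' @param n_nodes Number of genes.
#' @param n_edges Number of directed edges (at most `n_nodes (n_nodes-1)/2`).
#' @param n_samples Number of steady-state samples.
#' @param weight_range Length-2 interval for |structural coefficient|; the
#'   lower bound must be > 0.
#' @param noise_sd Standard deviation of each node's additive Gaussian noise.
#' @param seed Master seed; all generation is a pure function of it.
#' @return A list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_nodes = 100L, n_edges = 176L, n_samples = 100L,
                           weight_range = c(0.4, 1.0), noise_sd = 1.0,
                           seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  n_edges <- as.integer(n_edges)
  n_samples <- as.integer(n_samples)
  if (n_nodes < 2) stop("`n_nodes` must be >= 2")
  if (n_edges < 0 || n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("`n_edges` must lie in [0, n_nodes(n_nodes-1)/2]")
  }
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  if (length(weight_range) != 2 || weight_range[1] <= 0 ||
    weight_range[2] < weight_range[1]) {
    stop("`weight_range` must be 0 < lower <= upper")
  }
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  structure(
    list(
      n_nodes = n_nodes, n_edges = n_edges, n_samples = n_samples,
      weight_range = as.numeric(weight_range), noise_sd = noise_sd,
      seed = seed
    ),
    class = "benchmark_spec"
  )
}

#' Random sparse DAG
#'
#' Samples a uniformly random topological order over the gene identifiers and
#' then `n_edges` distinct forward pairs uniformly at random, so the result
#' is acyclic by construction.
#'
#' @param spec A [benchmark_spec()].
#' @return A [true_dag()].
#' @export
random_dag <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  p <- spec$n_nodes
  nodes <- sprintf("G%0*d", nchar(p), seq_len(p))
  with_seed(derive_seed(spec$seed, 1), {
    topo <- sample(nodes)
    npairs <- p * (p - 1) / 2
    sel <- sample.int(npairs, spec$n_edges)
    # map linear index over i<j pairs to (i, j) positions in topo
    ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    ut <- ut[order(ut[, 2], ut[, 1]), , drop = FALSE] # column-major = which() order
    edges <- cbind(topo[ut[sel, 1]], topo[ut[sel, 2]])
    true_dag(nodes, edges)
  })
}

#' Sample linear-Gaussian expression data from a DAG
#'
#' Each gene is a weighted sum of its parents plus independent Gaussian
#' noise, generated in topological order; columns are i.i.d. steady-state
#' samples. Edge weights are drawn uniformly from
#' `[-upper, -lower] U [lower, upper]` and are fixed per dataset. Values are
#' not standardized (the correlation-based tests are scale-invariant).
#'
#' @param dag A [true_dag()].
#' @param spec A [benchmark_spec()] (uses `n_samples`, `weight_range`,
#'   `noise_sd`, `seed`).
#' @return An [expression_dataset()] with attribute `weights` (named by
#'   "parent->child").
#' @export
sample_linear_gaussian <- function(dag, spec) {
  stopifnot(inherits(dag, "true_dag"), inherits(spec, "benchmark_spec"))
  p <- length(dag$nodes)
  n <- spec$n_samples
  with_seed(derive_seed(spec$seed, 2), {
    m <- nrow(dag$edges)
    w <- runif(m, spec$weight_range[1], spec$weight_range[2]) *
      sample(c(-1, 1), m, replace = TRUE)
    X <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, dag$nodes))
    for (v in dag$order) {
      ein <- which(dag$edges[, 2] == v)
      X[, v] <- rnorm(n, sd = spec$noise_sd)
      if (length(ein)) {
        X[, v] <- X[, v] +
          X[, dag$edges[ein, 1], drop = FALSE] %*% w[ein]
      }
    }
    out <- expression_dataset(t(X), variables = dag$nodes)
    attr(out, "weights") <- stats::setNames(
      w,
      if (m) paste0(dag$edges[, 1], "->", dag$edges[, 2]) else character(0)
    )
    out
  })
}

#' Generate a complete synthetic benchmark
#'
#' Bundles a random DAG, a linear-Gaussian expression dataset and the gold
#' standard (the DAG's skeleton). All three are a pure function of the
#' spec's seed and can be written to the package's text formats with
#' [write_expression()] and [write_edge_list()].
#'
#' @param spec A [benchmark_spec()].
#' @return A list of class `benchmark` with `data` ([expression_dataset()]),
#'   `gold` ([gold_standard()]), `dag` ([true_dag()]), and `spec`.
#' @export
make_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  dag <- random_dag(spec)
  data <- sample_linear_gaussian(dag, spec)
  gold <- dag_skeleton(dag)
  structure(
    list(data = data, gold = gold, dag = dag, spec = spec),
    class = "benchmark"
  )
}
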