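#' Synthetic benchmark evaluation sweeps
#'
#' Runs the package's standard replication experiments on a set of seeded
#' synthetic benchmarks (by default 10 draws at DREAM4 scale: 100 genes, 176
#' interactions, 100 samples) and reports bootstrap-ranked AUPRC for:
#'
#' * PC-lite at the given retention size;
#' * PriorPC with full true priors across the `alphas` grid;
#' * PriorPC at `alpha = 1` across true-prior `coverages` (coverage 1 reuses
#'   the full-prior run);
#' * PriorPC at `alpha = 0.5` with noise-corrupted full priors across
#'   `sigmas` (`sigma = 0` reuses the clean `alpha = 0.5` run);
#' * at 50% coverage and `alpha = 1`, AUPRC restricted to the neutral pairs
#'   (belief exactly 0.5) for both PriorPC and PC-lite.
#'
#' All randomness (benchmarks, priors, bootstrap resamples) is derived from
#' `seed`.
#'
#' @param seed Master seed.
#' @param n_benchmarks Number of independent benchmark draws.
#' @param K Bootstrap resamples per run.
#' @param spec A [benchmark_spec()] used as the template (its `seed` is
#'   replaced per draw).
#' @param n_keep Edges retained by PC-lite / PriorPC; default
#'   `round(3 * spec$n_edges)`.
#' @param alphas,coverages,sigmas Grids for the three sweeps.
#' @param config A [ci_config()].
#' @param progress Print one line per benchmark.
#' @return A data frame with one row per benchmark and one AUPRC column per
#'   experiment (`pclite`, `alpha_*`, `cov_*`, `sigma_*`,
#'   `neutral_priorpc`, `neutral_pclite`).
#' @export
benchmark_sweeps <- function(seed = 1, n_benchmarks = 10, K = 5,
                             spec = benchmark_spec(),
                             n_keep = round(3 * spec$n_edges),
                             alphas = c(0, 0.25, 0.5, 0.75, 1),
                             coverages = c(0.05, 0.25, 0.5, 1),
                             sigmas = c(0, 0.1, 0.2, 0.4),
                             config = ci_config(),
                             progress = FALSE) {
  rows <- vector("list", n_benchmarks)
  for (s in seq_len(n_benchmarks)) {
    bspec <- benchmark_spec(
      n_nodes = spec$n_nodes, n_edges = spec$n_edges,
      n_samples = spec$n_samples, weight_range = spec$weight_range,
      noise_sd = spec$noise_sd, seed = derive_seed(seed, 100 + s)
    )
    bm <- make_benchmark(bspec)
    gold <- bm$gold
    boot <- function(algo) {
      bootstrap_rank(bm$data, algo, K = K, seed = derive_seed(seed, 200 + s))
    }
    B_full <- true_priors(gold, coverage = 1, seed = derive_seed(seed, 300 + s))

    rk_pclite <- boot(function(d) pc_lite(d, n_keep = n_keep, config = config))
    row <- list(pclite = auprc(rk_pclite, gold))

    rk_alpha <- list()
    for (a in alphas) {
      rk_alpha[[as.character(a)]] <- boot(function(d) {
        priorpc_skeleton(d, B_full, alpha = a, n_keep = n_keep, config = config)
      })
      row[[paste0("alpha_", a)]] <- auprc(rk_alpha[[as.character(a)]], gold)
    }

    for (cv in coverages) {
      if (cv == 1 && "1" %in% names(rk_alpha)) {
        row[["cov_1"]] <- row[["alpha_1"]]
        next
      }
      Bc <- true_priors(gold,
        coverage = cv,
        seed = derive_seed(seed, 400 + s)
      )
      rk <- boot(function(d) {
        priorpc_skeleton(d, Bc, alpha = 1, n_keep = n_keep, config = config)
      })
      row[[paste0("cov_", cv)]] <- auprc(rk, gold)
      if (cv == 0.5) {
        en <- restrict_nodes(gold)
        ap <- all_pairs(en)
        neutral <- ap[Bc[ap] == 0.5, , drop = FALSE]
        row$neutral_priorpc <- auprc(rk, gold, pairs = neutral)
        row$neutral_pclite <- auprc(rk_pclite, gold, pairs = neutral)
      }
    }

    for (sg in sigmas) {
      if (sg == 0 && "0.5" %in% names(rk_alpha)) {
        row[["sigma_0"]] <- row[["alpha_0.5"]]
        next
      }
      Bn <- noisy_priors(
        B_full, gold,
        noise_model(sg, seed = derive_seed(seed, 500 + s))
      )
      rk <- boot(function(d) {
        priorpc_skeleton(d, Bn, alpha = 0.5, n_keep = n_keep, config = config)
      })
      row[[paste0("sigma_", sg)]] <- auprc(rk, gold)
    }
    rows[[s]] <- as.data.frame(row, check.names = FALSE)
    if (progress) {
      message("benchmark ", s, "/", n_benchmarks, " done")
    }
  }
  do.call(rbind, rows)
}

#' Skeleton recovery with a perfect CI oracle
#'
#' Draws random sparse DAGs, runs the PC skeleton phase with the exact
#' d-separation oracle under several random variable orderings each, and
#' reports the fraction of runs recovering the true skeleton exactly. With
#' perfect tests this fraction is 1 regardless of ordering.
#'
#' @param seed Master seed.
#' @param n_graphs Number of random DAGs.
#' @param n_orderings Random orderings tried per DAG.
#' @param max_nodes,max_edges Upper bounds for the sampled graph sizes.
#' @return A list with `exact` (count of exact recoveries), `total`, and
#'   `rate`.
#' @export
oracle_recovery_rate <- function(seed = 1, n_graphs = 100, n_orderings = 5,
                                 max_nodes = 10, max_edges = 15) {
  exact <- 0L
  total <- 0L
  for (g in seq_len(n_graphs)) {
    gseed <- derive_seed(seed, 600 + g)
    dag <- with_seed(gseed, {
      n_nodes <- sample(5:max_nodes, 1)
      n_edges <- min(sample(3:max_edges, 1), choose(n_nodes, 2))
      spec <- benchmark_spec(
        n_nodes = n_nodes, n_edges = n_edges,
        n_samples = 10, seed = gseed
      )
      random_dag(spec)
    })
    truth <- dag_skeleton(dag)$edges
    ci <- dsep_oracle(dag)
    for (r in seq_len(n_orderings)) {
      ord <- with_seed(derive_seed(gseed, r), sample(dag$nodes))
      sk <- pc_skeleton(ci, variables = dag$nodes, ordering = ord)
      total <- total + 1L
      exact <- exact + identical(sk$edges, truth)
    }
  }
  list(exact = exact, total = total, rate = exact / total)
}

#' Order dependence of sample-based PC
#'
#' Runs the PC skeleton phase on one seeded benchmark under several random
#' variable orderings and counts the distinct skeletons obtained. With
#' imperfect finite-sample CI tests the output depends on the ordering, so
#' more than one distinct skeleton is expected.
#'
#' @param seed Master seed.
#' @param n_orderings Number of random orderings.
#' @param spec Benchmark to run on (default: 50 genes, 75 edges, 30 samples).
#' @param config A [ci_config()].
#' @return A list with `n_distinct` and the per-ordering edge counts.
#' @export
order_dependence <- function(seed = 1, n_orderings = 10,
                             spec = benchmark_spec(
                               n_nodes = 50, n_edges = 75,
                               n_samples = 30, seed = derive_seed(seed, 700)
                             ),
                             config = ci_config()) {
  bm <- make_benchmark(spec)
  fingerprints <- character(n_orderings)
  n_edges <- integer(n_orderings)
  for (k in seq_len(n_orderings)) {
    ord <- with_seed(derive_seed(seed, 800 + k), sample(bm$data$variables))
    sk <- pc_skeleton(bm$data, ordering = ord, config = config)
    fingerprints[k] <- paste(c(t(sk$edges)), collapse = ",")
    n_edges[k] <- nrow(sk$edges)
  }
  list(n_distinct = length(unique(fingerprints)), n_edges = n_edges)
}
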