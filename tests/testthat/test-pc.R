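test_that("oracle-driven PC recovers textbook skeletons", {
  chain <- true_dag(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
  sk <- pc_skeleton(dsep_oracle(chain), variables = chain$nodes)
  expect_equal(unname(sk$edges), cbind(c("A", "B"), c("B", "C")))
  # the spurious A-C edge must fall at order 1 with sepset {B}
  seps <- attr(sk, "sepsets")
  expect_equal(seps[["A\rC"]], "B")

  collider <- true_dag(c("A", "B", "C"), cbind(c("A", "B"), c("C", "C")))
  sk2 <- pc_skeleton(dsep_oracle(collider), variables = collider$nodes)
  expect_equal(unname(sk2$edges), cbind(c("A", "B"), c("C", "C")))
  # A-B is marginally independent: removed at order 0 (empty sepset)
  expect_equal(attr(sk2, "sepsets")[["A\rB"]], character(0))

  empty <- true_dag(c("A", "B", "C"))
  sk3 <- pc_skeleton(dsep_oracle(empty), variables = empty$nodes)
  expect_equal(nrow(sk3$edges), 0)
})

test_that("oracle PC is exact for random sparse DAGs under any ordering", {
  for (seed in 1:10) {
    dag <- random_small_dag(
      n_nodes = sample(5:10, 1),
      n_edges = sample(4:12, 1),
      seed = seed, max_deg = 4
    )
    truth <- dag_skeleton(dag)
    ci <- dsep_oracle(dag)
    set.seed(seed + 500)
    for (rep in 1:5) {
      ordering <- sample(dag$nodes)
      sk <- pc_skeleton(ci, variables = dag$nodes, ordering = ordering)
      expect_identical(sk$edges, truth$edges,
        info = sprintf("seed %d rep %d", seed, rep)
      )
    }
  }
})

test_that("compiled and generic scans produce identical skeletons", {
  for (seed in 1:4) {
    bm <- make_benchmark(benchmark_spec(
      n_nodes = 12, n_edges = 14,
      n_samples = 40, seed = seed
    ))
    cfg <- ci_config(t = 0.5)
    fast <- pc_skeleton(bm$data, config = cfg)
    slow <- pc_skeleton(gaussian_ci_test(bm$data, cfg),
      variables = bm$data$variables, config = cfg
    )
    expect_identical(fast$edges, slow$edges)
    expect_identical(attr(fast, "n_tests"), attr(slow, "n_tests"))
    # and under a non-default ordering
    ord <- with_seed_test(seed, sample(bm$data$variables))
    fast2 <- pc_skeleton(bm$data, ordering = ord, config = cfg)
    slow2 <- pc_skeleton(gaussian_ci_test(bm$data, cfg),
      variables = bm$data$variables, ordering = ord, config = cfg
    )
    expect_identical(fast2$edges, slow2$edges)
  }
})

test_that("CI workload never exceeds the naive all-subsets count", {
  bm <- make_benchmark(benchmark_spec(
    n_nodes = 10, n_edges = 12,
    n_samples = 50, seed = 3
  ))
  sk <- pc_skeleton(bm$data)
  nt <- attr(sk, "n_tests")
  p <- 10
  # naive bound: every ordered pair times all subsets of the other p - 2
  # variables at each order
  naive <- sapply(as.integer(names(nt)), function(ell) {
    p * (p - 1) * choose(p - 2, ell)
  })
  expect_true(all(nt <= naive))
})

test_that("with noisy finite-sample tests the output depends on ordering", {
  bm <- make_benchmark(benchmark_spec(
    n_nodes = 50, n_edges = 75,
    n_samples = 30, seed = 7
  ))
  skeletons <- lapply(1:6, function(k) {
    ord <- with_seed_test(k, sample(bm$data$variables))
    paste(skeleton_edge_keys(pc_skeleton(bm$data, ordering = ord)),
      collapse = ";"
    )
  })
  expect_gt(length(unique(unlist(skeletons))), 1)
})

test_that("pc_lite seeds with top correlations and skips order 0", {
  d <- toy_dataset(seed = 21, p = 4, n = 25)
  st <- correlation_stats(d)
  # find the weakest pair
  C <- st$C
  diag(C) <- NA
  worst <- which(C == min(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
  worst_pair <- sort(rownames(C)[worst])
  sk <- pc_lite(d, n_keep = 5, config = ci_config(t = 1e-9))
  # with an extreme threshold nothing is removed after seeding, so the
  # skeleton is exactly the top-5 pairs; the weakest pair is absent
  expect_equal(nrow(sk$edges), 5)
  expect_false(any(sk$edges[, 1] == worst_pair[1] &
    sk$edges[, 2] == worst_pair[2]))

  # n_keep = all pairs behaves like complete-start PC without order 0
  cfg <- ci_config(t = 0.3)
  sk_all <- pc_lite(d, n_keep = 6, config = cfg)
  init <- matrix(TRUE, 4, 4)
  diag(init) <- FALSE
  manual <- priorpc:::run_pc_scan_fast(
    R = st$R, n = d$n, variables = d$variables,
    ordering = sort(d$variables), config = cfg, adj = init, min_order = 1L
  )
  expect_identical(sk_all$edges, manual$edges)

  # over-large n_keep warns and keeps all pairs
  expect_warning(sk_over <- pc_lite(d, n_keep = 10, config = cfg), "exceeds")
  expect_identical(sk_over$edges, sk_all$edges)
})

test_that("pc_lite seeds exactly n_keep edges at benchmark scale", {
  bm <- make_benchmark(benchmark_spec(seed = 2))
  sk <- pc_lite(bm$data, n_keep = 600, config = ci_config(t = 1e-12))
  expect_equal(nrow(attr(sk, "initial_edges")), 600)
  expect_equal(nrow(sk$edges), 600) # threshold ~ 0 removes nothing
})
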