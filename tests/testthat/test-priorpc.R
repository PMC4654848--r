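worked_stats <- function() {
  C <- matrix(c(1, .8, .2, .8, 1, .4, .2, .4, 1), 3, 3,
    dimnames = list(c("x", "y", "z"), c("x", "y", "z"))
  )
  structure(
    list(
      C = C, R = C, mu = (rowSums(C) - 1) / 2,
      sigma = apply(C, 1, function(r) sd(r[r != 1])),
      variables = colnames(C), n = 50, lambda = 0
    ),
    class = "correlation_stats"
  )
}

test_that("data score reproduces the hand-worked 3x3 example", {
  ds <- data_score(worked_stats())
  # mu = (0.5, 0.6, 0.3); d_12 = (0.3/0.5)(0.2/0.4), d_13 = (0.3/0.5)(0.1/0.7)
  expect_equal(ds$d["x", "y"], 0.3, tolerance = 1e-12)
  expect_equal(ds$d["x", "z"], 0.6 / 7, tolerance = 1e-12)
  expect_equal(ds$d, t(ds$d))
  expect_true(all(is.na(diag(ds$d))))
  # e uses sigma in place of the 1 - mu normalization
  st <- worked_stats()
  expect_equal(
    ds$e["x", "y"],
    abs((0.8 - st$mu[["x"]]) / st$sigma[["x"]]) *
      abs((0.8 - st$mu[["y"]]) / st$sigma[["y"]]),
    tolerance = 1e-12
  )
})

test_that("data score vanishes when a correlation equals the row mean", {
  st <- worked_stats()
  st$C["x", "y"] <- st$C["y", "x"] <- st$mu[["x"]]
  ds <- data_score(st)
  expect_equal(ds$d["x", "y"], 0)
})

test_that("data score is invariant to sample order and sign flips", {
  d <- toy_dataset(seed = 31, p = 6, n = 40)
  base <- data_score(correlation_stats(d))$d
  # permute samples
  perm <- expression_dataset(d$values[, sample(d$n)], d$variables)
  expect_equal(data_score(correlation_stats(perm))$d, base, tolerance = 1e-12)
  # flip one gene's sign
  flipped_vals <- d$values
  flipped_vals[2, ] <- -flipped_vals[2, ]
  flip <- expression_dataset(flipped_vals, d$variables)
  expect_equal(data_score(correlation_stats(flip))$d, base, tolerance = 1e-12)
})

test_that("confidence scores are the exact linear prior/data mix", {
  d <- toy_dataset(seed = 8, p = 5, n = 30)
  ds <- data_score(correlation_stats(d))
  B <- true_priors(gold_standard(d$variables, cbind("g1", "g2")), seed = 4)
  s0 <- confidence_scores(B, ds, alpha = 0)$s
  s1 <- confidence_scores(B, ds, alpha = 1)$s
  off <- upper.tri(s0)
  expect_equal(s0[off], ds$d[off])
  expect_equal(s1[off], unclass(B)[off])
  for (a in c(0.25, 0.5, 0.75)) {
    sa <- confidence_scores(B, ds, alpha = a)$s
    expect_equal(sa[off], a * unclass(B)[off] + (1 - a) * ds$d[off],
      tolerance = 1e-12
    )
  }
  expect_equal(confidence_scores(B, ds, 0.5)$s["g1", "g2"],
    0.5 * B["g1", "g2"] + 0.5 * ds$d["g1", "g2"],
    tolerance = 1e-12
  )
  expect_error(confidence_scores(B, ds, alpha = 1.2), "\\[0, 1\\]")
})

test_that("discarding keeps the top-scored pairs with lexicographic ties", {
  vars <- c("a", "b", "c", "d", "e")
  s <- matrix(0, 5, 5, dimnames = list(vars, vars))
  vals <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  s[upper.tri(s)] <- vals
  s <- s + t(s)
  kept <- discard_worst(s, 6)
  expect_equal(nrow(kept), 6)
  expect_equal(kept$score, sort(s[upper.tri(s)], decreasing = TRUE)[1:6])

  # all-equal scores: first n_keep pairs in lexicographic order
  s2 <- matrix(1, 5, 5, dimnames = list(vars, vars))
  kept2 <- discard_worst(s2, 4)
  expect_equal(kept2$from, c("a", "a", "a", "a"))
  expect_equal(kept2$to, c("b", "c", "d", "e"))

  expect_error(discard_worst(s, 2), ">= 3")
  expect_warning(discard_worst(s, 99), "exceeds")
})

test_that("tier assignment splits into near-equal thirds by score", {
  mk <- function(m) {
    data.frame(
      from = sprintf("a%02d", seq_len(m)),
      to = sprintf("b%02d", seq_len(m)),
      score = rev(seq_len(m))
    )
  }
  t600 <- assign_tiers(mk(600))
  expect_equal(sapply(t600, nrow), c(strong = 200, average = 200, weak = 200))
  t7 <- assign_tiers(mk(7))
  expect_equal(sapply(t7, nrow), c(strong = 3, average = 2, weak = 2))
  t3 <- assign_tiers(mk(3))
  expect_equal(sapply(t3, nrow), c(strong = 1, average = 1, weak = 1))
  expect_equal(t3$strong$score, 3) # strong = argmax s
  # partition: no pair in two tiers, union = input
  all_keys <- unname(unlist(lapply(t7, function(x) paste(x$from, x$to))))
  expect_equal(sort(all_keys), sort(paste(mk(7)$from, mk(7)$to)))
})

test_that("priorpc with alpha 0 ignores the prior entirely", {
  bm <- make_benchmark(benchmark_spec(
    n_nodes = 15, n_edges = 18,
    n_samples = 40, seed = 11
  ))
  B_flat <- prior_matrix(variables = bm$data$variables)
  B_other <- unclass(B_flat)
  B_other[upper.tri(B_other)] <- 0.9
  B_other <- prior_matrix((B_other + t(B_other)) / 2)
  sk1 <- priorpc_skeleton(bm$data, B_flat, alpha = 0, n_keep = 30)
  sk2 <- priorpc_skeleton(bm$data, B_other, alpha = 0, n_keep = 30)
  sk3 <- priorpc_skeleton(bm$data, alpha = 0, n_keep = 30) # default prior
  expect_identical(sk1$edges, sk2$edges)
  expect_identical(sk1$edges, sk3$edges)
})

test_that("with a perfect CI oracle true edges survive and exact retention recovers truth", {
  # perfect tests never separate a truly adjacent pair, so whenever the
  # retained set contains the true skeleton the output contains it too;
  # when the retained set IS the true skeleton, the output is exact.
  # (Retained supersets can leave extra edges: a marginally independent pair
  # whose only separating set is empty is untestable once order-0 tests are
  # replaced by the discard step.)
  bm <- make_benchmark(benchmark_spec(
    n_nodes = 10, n_edges = 10,
    n_samples = 30, seed = 13
  ))
  ci <- dsep_oracle(bm$dag)
  truth_keys <- paste(bm$gold$edges[, 1], bm$gold$edges[, 2])
  for (a in c(0, 0.5, 1)) {
    B <- true_priors(bm$gold, coverage = 1, seed = 20 + a * 10)
    sk <- priorpc_skeleton(bm$data, B,
      alpha = a, n_keep = 45, ci = ci
    ) # n_keep = all pairs: retained superset guaranteed
    expect_true(all(truth_keys %in% paste(sk$edges[, 1], sk$edges[, 2])),
      info = paste("alpha", a)
    )
  }
  # exact retention: with full true priors at alpha = 1, the top-|E| edges
  # are exactly the gold edges, and perfect tests remove none of them
  B1 <- true_priors(bm$gold, coverage = 1, seed = 7)
  sk_exact <- priorpc_skeleton(bm$data, B1,
    alpha = 1,
    n_keep = nrow(bm$gold$edges), ci = ci
  )
  expect_identical(sk_exact$edges, bm$gold$edges)
})

test_that("tiered scan uses one shared working graph", {
  # an edge removed in the weak tier must not reappear, and the number of
  # retained edges bounds the output
  bm <- make_benchmark(benchmark_spec(
    n_nodes = 20, n_edges = 25,
    n_samples = 50, seed = 17
  ))
  B <- true_priors(bm$gold, coverage = 1, seed = 2)
  sk <- priorpc_skeleton(bm$data, B, alpha = 0.5, n_keep = 75)
  retained <- attr(sk, "retained")
  expect_lte(nrow(sk$edges), 75)
  keys_out <- paste(sk$edges[, 1], sk$edges[, 2])
  keys_in <- paste(retained$from, retained$to)
  expect_true(all(keys_out %in% keys_in))
  # tiers partition the retained set
  tiers <- attr(sk, "tiers")
  tier_keys <- unname(unlist(lapply(tiers, function(x) paste(x$from, x$to))))
  expect_equal(sort(tier_keys), sort(keys_in))
})

test_that("compiled and generic tier scans agree", {
  bm <- make_benchmark(benchmark_spec(
    n_nodes = 12, n_edges = 15,
    n_samples = 35, seed = 23
  ))
  B <- true_priors(bm$gold, coverage = 1, seed = 6)
  cfg <- ci_config(t = 0.5)
  fast <- priorpc_skeleton(bm$data, B, alpha = 0.5, n_keep = 30, config = cfg)
  slow <- priorpc_skeleton(bm$data, B,
    alpha = 0.5, n_keep = 30, config = cfg,
    ci = gaussian_ci_test(bm$data, cfg)
  )
  expect_identical(fast$edges, slow$edges)
})
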