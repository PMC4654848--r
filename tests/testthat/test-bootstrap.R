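# independent step-wise AUPRC / pairwise AUROC implementations for
# cross-checking
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

auprc_bruteforce <- function(scores, labels) {
  P <- sum(labels)
  area <- 0
  prev_rec <- 0
  for (thr in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= thr
    tp <- sum(labels & sel)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

mk_eval <- function(scores, labels, nodes) {
  # build a ranking + gold over `nodes` whose pair scores/labels are given in
  # lexicographic pair order
  pairs <- t(combn(sort(nodes), 2))
  gold <- gold_standard(nodes, pairs[labels, , drop = FALSE])
  rk <- ranked_edges(pairs[scores > 0, 1], pairs[scores > 0, 2],
    scores[scores > 0]
  )
  list(rk = rk, gold = gold)
}

test_that("auroc and auprc match brute-force oracles on random instances", {
  nodes <- sprintf("v%02d", 1:9) # 36 pairs
  for (seed in 1:10) {
    set.seed(seed)
    npairs <- choose(9, 2)
    scores <- sample(0:6, npairs, replace = TRUE)
    labels <- runif(npairs) < 0.3
    if (!any(labels) || all(labels)) next
    ev <- mk_eval(scores, labels, nodes)
    expect_equal(auroc(ev$rk, ev$gold, eval_nodes = nodes),
      auroc_bruteforce(scores, labels),
      tolerance = 1e-12, info = paste("seed", seed)
    )
    expect_equal(auprc(ev$rk, ev$gold, eval_nodes = nodes),
      auprc_bruteforce(scores, labels),
      tolerance = 1e-12, info = paste("seed", seed)
    )
  }
})

test_that("metric edge cases follow the standard conventions", {
  nodes <- c("a", "b", "c", "d")
  pairs <- t(combn(nodes, 2)) # 6 pairs
  gold <- gold_standard(nodes, pairs[1:2, ])
  # perfect ranking
  rk <- ranked_edges(pairs[1:2, 1], pairs[1:2, 2], c(5, 4))
  expect_equal(auroc(rk, gold, nodes), 1)
  expect_equal(auprc(rk, gold, nodes), 1)
  # all-tied scores: AUROC 1/2 by mid-rank
  rk2 <- ranked_edges(pairs[, 1], pairs[, 2], rep(1, 6))
  expect_equal(auroc(rk2, gold, nodes), 0.5)
  # AUPRC baseline: single positive ranked last among m pairs -> 1/m
  gold3 <- gold_standard(nodes, pairs[6, , drop = FALSE])
  rk3 <- ranked_edges(pairs[1:5, 1], pairs[1:5, 2], 6:2)
  expect_equal(auprc(rk3, gold3, nodes), 1 / 6)
  # no positives / no negatives are undefined
  expect_error(
    auroc(rk, gold_standard(nodes, pairs), nodes),
    "undefined"
  )
  # the uninformative all-tied ranking attains exactly the positive rate
  for (npos in 1:3) {
    labels <- seq_len(6) <= npos
    ev <- mk_eval(rep(1, 6), labels, nodes)
    expect_equal(auprc(ev$rk, ev$gold, nodes), npos / 6, tolerance = 1e-12)
  }
})

test_that("auroc is invariant to monotone score transforms", {
  nodes <- sprintf("v%d", 1:7)
  set.seed(4)
  npairs <- choose(7, 2)
  scores <- runif(npairs)
  labels <- runif(npairs) < 0.4
  ev1 <- mk_eval(scores, labels, nodes)
  ev2 <- mk_eval(exp(3 * scores), labels, nodes)
  expect_equal(
    auroc(ev1$rk, ev1$gold, nodes),
    auroc(ev2$rk, ev2$gold, nodes),
    tolerance = 1e-12
  )
})

test_that("evaluation restricts to gold-connected nodes", {
  nodes <- c("a", "b", "c", "d", "e")
  gold <- gold_standard(nodes, cbind("a", "b"))
  expect_equal(restrict_nodes(gold), c("a", "b"))
  expect_error(restrict_nodes(gold_standard(nodes)), "no edges")
  # pairs touching isolated nodes are never counted
  gold2 <- gold_standard(nodes, cbind(c("a", "b"), c("b", "c")))
  with_de <- ranked_edges(c("a", "c", "d"), c("b", "b", "e"), c(2, 1, 99))
  without_de <- ranked_edges(c("a", "c"), c("b", "b"), c(2, 1))
  # eval set = {a, b, c}; pair (d, e) outranking everything changes nothing
  expect_equal(auroc(with_de, gold2), auroc(without_de, gold2))
  expect_equal(auprc(with_de, gold2), auprc(without_de, gold2))
})

test_that("bootstrap ranking counts skeleton frequency deterministically", {
  bm <- make_benchmark(benchmark_spec(
    n_nodes = 12, n_edges = 14,
    n_samples = 40, seed = 19
  ))
  algo <- function(d) pc_lite(d, n_keep = 20)
  # K = 1: ranking is the indicator of the single skeleton's edges
  rk1 <- bootstrap_rank(bm$data, algo, K = 1, seed = 5)
  expect_true(all(rk1$score == 1))
  # frequencies bounded by K; ranking sorted by frequency then pair
  rk <- bootstrap_rank(bm$data, algo, K = 7, seed = 5)
  expect_true(all(rk$score >= 1 & rk$score <= 7))
  expect_true(all(diff(rk$score) <= 0))
  # identical reruns under the same master seed
  rk_again <- bootstrap_rank(bm$data, algo, K = 7, seed = 5)
  expect_identical(rk, rk_again)
  # different seed changes the resamples
  rk_other <- bootstrap_rank(bm$data, algo, K = 7, seed = 6)
  expect_false(identical(rk$score, rk_other$score) &&
    identical(rk$from, rk_other$from))
  # failing algorithm reports the resample index
  expect_error(
    bootstrap_rank(bm$data, function(d) stop("boom"), K = 3, seed = 1),
    "resample 1"
  )
})

test_that("an always-present edge outranks an intermittent one", {
  # two genes tied by a strong edge vs. a weak one: the strong edge must
  # appear in every bootstrap skeleton
  set.seed(77)
  n <- 60
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, sd = 0.1)
  z <- 0.3 * x + rnorm(n)
  w <- rnorm(n)
  d <- expression_dataset(rbind(x = x, y = y, z = z, w = w))
  rk <- bootstrap_rank(d, function(dd) pc_lite(dd, n_keep = 3), K = 10, seed = 2)
  expect_equal(rk$from[1], "x")
  expect_equal(rk$to[1], "y")
  expect_equal(rk$score[1], 10)
})
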