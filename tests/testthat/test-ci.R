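test_that("fisher z-transform matches closed forms and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2, tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-14)
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("ci statistic matches direct evaluation and is monotone", {
  expect_equal(ci_statistic(0, 100, 3), 0)
  expect_equal(ci_statistic(0.01, 50, 2),
    abs(atanh(0.01)) * sqrt(45),
    tolerance = 1e-10
  )
  expect_equal(ci_statistic(0.5, 50, 0),
    (log(3) / 2) * sqrt(47),
    tolerance = 1e-10
  )
  expect_error(ci_statistic(0.1, 5, 3), "insufficient samples")
  # monotone in |r| at fixed n, k and in n at fixed r, k
  rs <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(sapply(rs, ci_statistic, n = 40, k = 1)) > 0))
  ns <- seq(10, 200, by = 10)
  expect_true(all(diff(sapply(ns, function(n) ci_statistic(0.3, n, 1))) > 0))
})

test_that("partial correlation reduces to Pearson and matches recursion", {
  d <- toy_dataset(seed = 7, p = 6, n = 60)
  X <- t(d$values)
  expect_equal(partial_correlation(d, "g1", "g2"),
    cor(X[, "g1"], X[, "g2"]),
    tolerance = 1e-12
  )
  # against the textbook recursion formula, |Y| = 1 and 2
  combos <- list(
    c("g1", "g2", "g3"),
    c("g2", "g5", "g1"),
    c("g1", "g4", "g2", "g3"),
    c("g3", "g6", "g1", "g5")
  )
  for (cb in combos) {
    got <- partial_correlation(d, cb[1], cb[2], cb[-(1:2)])
    want <- pcor_recursive(X, cb[1], cb[2], cb[-(1:2)])
    expect_equal(got, want, tolerance = 1e-8)
  }
  # symmetry in (i, j)
  expect_equal(
    partial_correlation(d, "g1", "g2", c("g3", "g4")),
    partial_correlation(d, "g2", "g1", c("g3", "g4")),
    tolerance = 1e-10
  )
  # compiled submatrix-inversion route agrees with the R route
  st <- correlation_stats(d)
  idx <- setNames(seq_along(d$variables), d$variables)
  for (cb in combos) {
    got_cpp <- priorpc:::pcor_from_cor_cpp(
      st$R, idx[[cb[1]]], idx[[cb[2]]],
      as.integer(idx[cb[-(1:2)]])
    )
    expect_equal(got_cpp, partial_correlation(d, cb[1], cb[2], cb[-(1:2)]),
      tolerance = 1e-10
    )
  }
})

test_that("conditioning on the middle of a chain removes dependence", {
  set.seed(42)
  n <- 10000
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  z <- 0.7 * y + rnorm(n)
  d <- expression_dataset(rbind(X = x, Y = y, Z = z))
  r <- partial_correlation(d, "X", "Z", "Y")
  expect_lt(abs(r), 3 / sqrt(n))
  expect_gt(abs(partial_correlation(d, "X", "Z")), 0.3)
})

test_that("independence decisions follow the threshold rule", {
  cfg <- ci_config(t = 0.1)
  # a pair engineered to sit just under / over the threshold
  set.seed(1)
  d <- toy_dataset(seed = 5, p = 4, n = 50)
  r <- partial_correlation(d, "g1", "g2")
  stat <- ci_statistic(r, 50, 0)
  expect_identical(
    is_independent(d, "g1", "g2", config = cfg),
    stat <= 0.1
  )
  # identical columns: dependent by the |r| ~ 1 convention
  m <- rbind(a = 1:30 + 0.5, b = 1:30 + 0.5, c = rnorm(30))
  dd <- expression_dataset(m)
  expect_false(is_independent(dd, "a", "b", config = cfg))
  # too-small samples: warning + dependent
  small <- toy_dataset(seed = 2, p = 6, n = 5)
  expect_warning(
    res <- is_independent(small, "g1", "g2", c("g3", "g4"), cfg),
    "dependent"
  )
  expect_false(res)
})

test_that("correlation stats validate input and summarize backgrounds", {
  d <- toy_dataset(seed = 9, p = 5, n = 30)
  st <- correlation_stats(d)
  expect_equal(unname(diag(st$C)), rep(1, 5))
  expect_equal(st$C, t(st$C))
  # mu_i over exactly p - 1 off-diagonal values
  i <- 2
  expect_equal(unname(st$mu[i]), mean(st$C[i, -i]), tolerance = 1e-12)
  expect_equal(unname(st$sigma[i]), sd(st$C[i, -i]), tolerance = 1e-12)
  # perfect correlation and sign removal
  m <- rbind(a = 1:10, b = (1:10) * 2, c = -(1:10), d = rnorm(10))
  st2 <- correlation_stats(expression_dataset(m))
  expect_equal(st2$C["a", "b"], 1)
  expect_equal(st2$C["a", "c"], 1)
  # zero-variance gene is named
  m2 <- rbind(a = rep(1, 10), b = rnorm(10))
  expect_error(correlation_stats(expression_dataset(m2)), "a")
  # matches direct Pearson on a random matrix
  set.seed(10)
  m3 <- matrix(rnorm(250), 5, dimnames = list(paste0("v", 1:5), NULL))
  st3 <- correlation_stats(expression_dataset(m3))
  expect_equal(unname(st3$C), unname(abs(cor(t(m3)))), tolerance = 1e-10)
})

test_that("shrinkage contracts off-diagonal correlations towards zero", {
  d <- toy_dataset(seed = 3, p = 8, n = 20)
  plain <- correlation_stats(d)
  shrunk <- correlation_stats(d, shrinkage = TRUE)
  expect_gt(shrunk$lambda, 0)
  expect_lt(shrunk$lambda, 1)
  off <- upper.tri(plain$R)
  expect_true(all(abs(shrunk$R[off]) <= abs(plain$R[off]) + 1e-12))
  expect_equal(unname(diag(shrunk$R)), rep(1, 8))
})

test_that("significance level converts to the documented threshold", {
  expect_equal(beta_to_threshold(0.01), qnorm(0.995), tolerance = 1e-12)
  expect_error(beta_to_threshold(0), "\\(0, 1\\)")
})
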