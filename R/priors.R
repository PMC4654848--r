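#' Gaussian prior-corruption model
#'
#' @param sigma Standard deviation (>= 0) of the Gaussian noise added to
#'   prior beliefs.
#' @param seed Optional RNG seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("`sigma` must be a non-negative number")
  }
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

# Uniform draws from (0.5, 1] (edge) or [0, 0.5) (non-edge); the boundary
# value 0.5 is excluded by rejection so priors never collide with the
# non-informative default.
draw_true_prior <- function(is_edge) {
  n <- length(is_edge)
  b <- numeric(n)
  b[is_edge] <- runif(sum(is_edge), 0.5, 1)
  b[!is_edge] <- runif(sum(!is_edge), 0, 0.5)
  while (any(bad <- b == 0.5)) {
    b[bad & is_edge] <- runif(sum(bad & is_edge), 0.5, 1)
    b[bad & !is_edge] <- runif(sum(bad & !is_edge), 0, 0.5)
  }
  b
}

#' True synthetic priors from a gold standard
#'
#' Assigns a "true" prior to a uniformly random fraction of all node pairs:
#' pairs that are gold-standard edges receive a belief sampled uniformly from
#' (0.5, 1], non-edges from [0, 0.5). All other pairs keep the
#' non-informative 0.5.
#'
#' @param gold A [gold_standard()].
#' @param coverage Fraction in `[0, 1]` of node pairs receiving a true prior.
#' @param seed Optional RNG seed (fixed seed gives a byte-identical matrix).
#' @return A [prior_matrix()] over `gold$nodes`.
#' @export
true_priors <- function(gold, coverage = 1, seed = NULL) {
  stopifnot(inherits(gold, "gold_standard"))
  if (!is.numeric(coverage) || coverage < 0 || coverage > 1) {
    stop("`coverage` must lie in [0, 1]")
  }
  pairs <- all_pairs(gold$nodes)
  npairs <- nrow(pairs)
  gold_keys <- skeleton_keys(gold)
  with_seed(seed, {
    n_sel <- round(coverage * npairs)
    sel <- if (n_sel) sort(sample.int(npairs, n_sel)) else integer(0)
    B <- prior_matrix(variables = gold$nodes)
    if (length(sel)) {
      is_edge <- pair_key(pairs[sel, 1], pairs[sel, 2]) %in% gold_keys
      b <- draw_true_prior(is_edge)
      B[cbind(pairs[sel, 1], pairs[sel, 2])] <- b
      B[cbind(pairs[sel, 2], pairs[sel, 1])] <- b
    }
    prior_matrix(unclass(B))
  })
}

#' Noise-corrupted priors
#'
#' Adds directional Gaussian corruption to every pair's belief: gold-standard
#' edges are moved downwards (\eqn{\hat b = b - |e|}), non-edges upwards
#' (\eqn{\hat b = b + |e|}) with \eqn{e \sim N(0, \sigma)} drawn
#' independently per pair; results are clamped to `[0, 1]` so the output
#' remains a valid belief matrix.
#'
#' @param B A [prior_matrix()] (e.g. from [true_priors()]).
#' @param gold The [gold_standard()] deciding the corruption direction.
#' @param noise A [noise_model()].
#' @return A corrupted [prior_matrix()].
#' @export
noisy_priors <- function(B, gold, noise) {
  stopifnot(
    inherits(B, "prior_matrix"), inherits(gold, "gold_standard"),
    inherits(noise, "noise_model")
  )
  vars <- rownames(B)
  if (!setequal(vars, gold$nodes)) {
    stop("prior matrix and gold standard have different node sets")
  }
  pairs <- all_pairs(vars)
  gold_keys <- skeleton_keys(gold)
  is_edge <- pair_key(pairs[, 1], pairs[, 2]) %in% gold_keys
  with_seed(noise$seed, {
    e <- abs(rnorm(nrow(pairs), 0, noise$sigma))
    b <- B[cbind(pairs[, 1], pairs[, 2])]
    bhat <- ifelse(is_edge, b - e, b + e)
    bhat <- pmin(1, pmax(0, bhat))
    out <- unclass(B)
    out[cbind(pairs[, 1], pairs[, 2])] <- bhat
    out[cbind(pairs[, 2], pairs[, 1])] <- bhat
    prior_matrix(out)
  })
}

#' Partially flipped priors
#'
#' The flipped-error comparison setup: a random fraction of the true
#' (gold-standard) edges receives a belief in (0.5, 1]; `n_false` additional
#' pairs, sampled from the remaining pairs, receive a true prior which is
#' then flipped via \eqn{b \leftarrow 1 - b} (so flipped edges end below 0.5
#' and flipped non-edges above 0.5); everything else stays at 0.5.
#'
#' @param gold A [gold_standard()].
#' @param true_edge_coverage Fraction in `[0, 1]` of gold edges given a
#'   correct prior.
#' @param n_false Number of additional pairs given a flipped prior.
#' @param seed Optional RNG seed.
#' @return A [prior_matrix()].
#' @export
flipped_priors <- function(gold, true_edge_coverage = 0.5, n_false = 0,
                           seed = NULL) {
  stopifnot(inherits(gold, "gold_standard"))
  if (true_edge_coverage < 0 || true_edge_coverage > 1) {
    stop("`true_edge_coverage` must lie in [0, 1]")
  }
  pairs <- all_pairs(gold$nodes)
  keys <- pair_key(pairs[, 1], pairs[, 2])
  gold_keys <- skeleton_keys(gold)
  edge_rows <- which(keys %in% gold_keys)
  with_seed(seed, {
    n_true <- round(true_edge_coverage * length(edge_rows))
    sel_true <- if (n_true) sort(sample(edge_rows, n_true)) else integer(0)
    rest <- setdiff(seq_len(nrow(pairs)), sel_true)
    if (n_false > length(rest)) {
      stop(
        "n_false (", n_false, ") exceeds the number of available pairs (",
        length(rest), ")"
      )
    }
    sel_false <- if (n_false) sort(sample(rest, n_false)) else integer(0)
    B <- prior_matrix(variables = gold$nodes)
    if (length(sel_true)) {
      b <- draw_true_prior(rep(TRUE, length(sel_true)))
      B[cbind(pairs[sel_true, 1], pairs[sel_true, 2])] <- b
      B[cbind(pairs[sel_true, 2], pairs[sel_true, 1])] <- b
    }
    if (length(sel_false)) {
      is_edge <- keys[sel_false] %in% gold_keys
      b <- 1 - draw_true_prior(is_edge)
      B[cbind(pairs[sel_false, 1], pairs[sel_false, 2])] <- b
      B[cbind(pairs[sel_false, 2], pairs[sel_false, 1])] <- b
    }
    prior_matrix(unclass(B))
  })
}
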