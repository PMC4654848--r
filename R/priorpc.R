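#' CLR-style data score for edge support
#'
#' Scores how far a pair's absolute correlation deviates from both genes'
#' correlation backgrounds. With `C` the absolute correlation matrix and
#' `mu[i]`, `sigma[i]` the mean and standard deviation of gene i's
#' off-diagonal absolute correlations, the unnormalized score is
#' \deqn{e_{ij} = \left|\frac{C_{ij}-\mu_i}{\sigma_i}\right| \times
#'       \left|\frac{C_{ij}-\mu_j}{\sigma_j}\right|}
#' and the normalized data score divides each factor by its value at
#' \eqn{C_{ii} = 1}:
#' \deqn{d_{ij} = \left|\frac{C_{ij}-\mu_i}{1-\mu_i}\right| \times
#'       \left|\frac{C_{ij}-\mu_j}{1-\mu_j}\right|.}
#' `d` is used only for ranking and is deliberately not clipped to `[0, 1]`
#' (it can exceed 1 when \eqn{C_{ij} < \mu_i} and \eqn{\mu_i > 0.5}).
#'
#' @param stats A [correlation_stats()] object.
#' @return A list of class `confidence_scores` with symmetric matrices `e`
#'   and `d` (diagonal `NA`) and the `variables`.
#' @export
data_score <- function(stats) {
  stopifnot(inherits(stats, "correlation_stats"))
  C <- stats$C
  mu <- stats$mu
  sigma <- stats$sigma
  if (any(mu >= 1)) {
    stop(
      "degenerate correlation profile (mu_i = 1) for: ",
      paste(stats$variables[mu >= 1], collapse = ", ")
    )
  }
  zero_sd <- sigma == 0
  if (any(zero_sd)) {
    warning(
      "constant correlation profile (sigma_i = 0) for: ",
      paste(stats$variables[zero_sd], collapse = ", "),
      "; their unnormalized scores are set to 0"
    )
  }
  dev <- sweep(C, 1, mu, "-") # C_ij - mu_i, by row
  zi <- abs(sweep(dev, 1, ifelse(zero_sd, Inf, sigma), "/"))
  zi[zero_sd, ] <- 0
  e <- zi * t(zi)
  di <- abs(sweep(dev, 1, 1 - mu, "/"))
  d <- di * t(di)
  diag(e) <- NA_real_
  diag(d) <- NA_real_
  dimnames(e) <- dimnames(d) <- list(stats$variables, stats$variables)
  structure(
    list(e = e, d = d, variables = stats$variables),
    class = "confidence_scores"
  )
}

#' Per-edge confidence scores mixing prior and data
#'
#' \eqn{s_{ij} = \alpha b_{ij} + (1-\alpha) d_{ij}}: the prior belief and the
#' data score are mixed linearly. `alpha = 1` ranks edges by prior only,
#' `alpha = 0` by data only; `alpha = 0.5` is the recommended default when
#' prior reliability is unknown.
#'
#' @param B A [prior_matrix()] aligned to the score variables.
#' @param scores A `confidence_scores` object from [data_score()], or a
#'   symmetric numeric matrix of data scores.
#' @param alpha Mixing weight in `[0, 1]`.
#' @return The input `scores` with an `s` matrix and `alpha` added.
#' @export
confidence_scores <- function(B, scores, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]")
  }
  d <- if (inherits(scores, "confidence_scores")) scores$d else as.matrix(scores)
  if (!all(dim(B) == dim(d))) {
    stop("prior matrix and data scores have mismatched dimensions")
  }
  vars <- rownames(d)
  if (!is.null(vars) && !is.null(rownames(B)) &&
    !identical(rownames(B), vars)) {
    if (!setequal(rownames(B), vars)) {
      stop("prior matrix variables do not match the data scores")
    }
    B <- B[vars, vars]
  }
  s <- alpha * unclass(B) + (1 - alpha) * d
  out <- if (inherits(scores, "confidence_scores")) {
    scores
  } else {
    list(d = d, variables = vars)
  }
  out$s <- s
  out$alpha <- alpha
  class(out) <- "confidence_scores"
  out
}

#' Discard the worst edges
#'
#' Ranks all node pairs by decreasing confidence score (ties broken
#' lexicographically by canonical pair) and retains the top `n_keep`; all
#' other pairs are permanently excluded. In PriorPC this replaces the
#' zero-order CI tests. `n_keep` is usually about three times the expected
#' edge count, feeding the three-tier schedule.
#'
#' @param scores A `confidence_scores` object with `s` filled, or a symmetric
#'   numeric matrix with dimnames.
#' @param n_keep Number of edges to retain (>= 3 so the tiers are non-empty).
#' @return A data frame `from`, `to`, `score`, sorted by score descending
#'   (ties lexicographic).
#' @export
discard_worst <- function(scores, n_keep) {
  s <- if (inherits(scores, "confidence_scores")) scores$s else as.matrix(scores)
  if (is.null(s)) stop("confidence scores `s` not computed yet")
  vars <- rownames(s)
  if (is.null(vars)) stop("score matrix needs dimnames")
  if (n_keep < 3) stop("`n_keep` must be >= 3 (non-empty tiers)")
  top_pairs_by_score(s, vars, n_keep)
}

#' Three-tier assignment of retained edges
#'
#' Splits the retained edges, sorted by confidence score descending (ties
#' lexicographic), into thirds: `strong` (top), `average` (middle), `weak`
#' (bottom). When the count is not divisible by 3 the remainder goes to the
#' earlier-listed tiers, so tier sizes differ by at most 1.
#'
#' @param retained Data frame from [discard_worst()] (`from`, `to`, `score`).
#' @return A list of class `tier_assignment` with data frames `strong`,
#'   `average`, `weak`.
#' @export
assign_tiers <- function(retained) {
  m <- nrow(retained)
  if (!m) stop("no retained edges to assign")
  o <- order(
    -retained$score, xtfrm_c(retained$from),
    xtfrm_c(retained$to)
  )
  retained <- retained[o, , drop = FALSE]
  base <- m %/% 3L
  rem <- m %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  cuts <- cumsum(sizes)
  structure(
    list(
      strong = retained[seq_len(cuts[1]), , drop = FALSE],
      average = retained[seq.int(cuts[1] + 1L, cuts[2]), , drop = FALSE],
      weak = retained[seq.int(cuts[2] + 1L, cuts[3]), , drop = FALSE]
    ),
    class = "tier_assignment"
  )
}

#' PriorPC skeleton estimation
#'
#' The full PriorPC pipeline: (1) compute the CLR-style data score from the
#' absolute correlation matrix; (2) mix it with the prior beliefs into
#' confidence scores \eqn{s_{ij} = \alpha b_{ij} + (1-\alpha) d_{ij}}; (3)
#' discard all but the top `n_keep` edges (replacing zero-order tests); (4)
#' split the survivors into weak / average / strong tiers; (5) run CI tests
#' of order 1..`max_order` tier by tier -- weak candidates first, strong
#' last -- on one shared working graph, so early removals of weakly believed
#' edges clean up the neighbourhoods used to test strongly believed ones.
#' Within a tier, edges are processed in increasing confidence order (ties
#' lexicographic).
#'
#' @param data An [expression_dataset()].
#' @param B A [prior_matrix()] over the same variables (default
#'   non-informative: all 0.5).
#' @param alpha Mixing weight in `[0, 1]`; 0.5 recommended when prior
#'   reliability is unknown.
#' @param n_keep Number of edges retained after discarding. Defaults to
#'   `round(3 * expected_edges)` when `expected_edges` is supplied.
#' @param expected_edges Expected number of true edges |E| (used only to
#'   default `n_keep`).
#' @param ordering,config As in [pc_skeleton()].
#' @param ci Optional CI callable `f(i, j, Y)` overriding the Gaussian
#'   partial-correlation test (e.g. [dsep_oracle()] for ground-truth
#'   experiments).
#' @return A [skeleton()] with attributes `tiers` (the `tier_assignment`),
#'   `scores` (`confidence_scores`), `n_tests`, `sepsets`.
#' @export
priorpc_skeleton <- function(data, B = NULL, alpha = 0.5, n_keep = NULL,
                             expected_edges = NULL, ordering = NULL,
                             config = ci_config(), ci = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(n_keep)) {
    if (is.null(expected_edges)) {
      stop("supply `n_keep` or `expected_edges` (n_keep defaults to 3|E|)")
    }
    n_keep <- round(3 * expected_edges)
  }
  if (is.null(B)) {
    B <- prior_matrix(variables = data$variables)
  }
  ordering <- check_ordering(ordering, data$variables)
  stats <- correlation_stats(data, shrinkage = config$shrinkage)
  scores <- confidence_scores(B, data_score(stats), alpha = alpha)
  retained <- discard_worst(scores, n_keep)
  tiers <- assign_tiers(retained)

  variables <- data$variables
  adj <- edges_to_adj(retained, variables)
  ord_idx <- match(ordering, variables)
  ord0 <- ord_idx - 1L
  n_tests <- integer(0)
  sepsets <- list()

  for (tier in c("weak", "average", "strong")) {
    edges_t <- tiers[[tier]]
    if (!nrow(edges_t)) next
    # least-believed edges first within the tier
    o <- order(
      edges_t$score, xtfrm_c(edges_t$from),
      xtfrm_c(edges_t$to)
    )
    edges_t <- edges_t[o, , drop = FALSE]
    fi <- match(edges_t$from, variables)
    ti <- match(edges_t$to, variables)
    # test the endpoint earlier in the ordering first
    pos <- match(seq_along(variables), ord_idx)
    swap <- pos[fi] > pos[ti]
    a_idx <- ifelse(swap, ti, fi)
    b_idx <- ifelse(swap, fi, ti)
    for (ell in seq_len(config$max_order)) {
      alive <- adj[cbind(a_idx, b_idx)]
      if (!any(alive)) break
      degs <- rowSums(adj)
      if (!any(pmax(degs[a_idx[alive]], degs[b_idx[alive]]) - 1L >= ell)) break
      if (is.null(ci)) {
        res <- tier_scan_cpp(
          stats$R, as.integer(stats$n), adj,
          cbind(a_idx - 1L, b_idx - 1L), as.integer(ell),
          config$t, ord0
        )
        adj <- res$adj
        tier_tests <- as.integer(res$n_tests)
        if (length(res$removed_i)) {
          rp <- canonical_pairs(
            variables[res$removed_i],
            variables[res$removed_j]
          )
          sep <- lapply(res$sepsets, function(s) variables[s])
          names(sep) <- pair_key(rp[, 1], rp[, 2])
          sepsets <- c(sepsets, sep)
        }
      } else {
        tier_tests <- 0L
        for (k in seq_along(a_idx)) {
          a <- a_idx[k]
          b <- b_idx[k]
          if (!adj[a, b]) next
          for (side in list(c(a, b), c(b, a))) {
            nbrs <- ord_idx[adj[side[1], ord_idx]]
            nbrs <- nbrs[nbrs != side[2]]
            if (length(nbrs) < ell) next
            hit <- find_sepset_generic(
              ci, variables, side[1], side[2],
              nbrs, ell, config$t
            )
            tier_tests <- tier_tests + hit$n_tests
            if (!is.null(hit$sepset)) {
              adj[a, b] <- adj[b, a] <- FALSE
              rp <- canonical_pairs(variables[a], variables[b])
              sepsets[[pair_key(rp[1, 1], rp[1, 2])]] <-
                variables[hit$sepset]
              break
            }
          }
          if (!adj[a, b]) next
        }
      }
      n_tests <- c(
        n_tests,
        stats::setNames(tier_tests, paste0(tier, ".", ell))
      )
    }
  }
  sk <- finish_skeleton(adj, variables, n_tests, sepsets)
  attr(sk, "tiers") <- tiers
  attr(sk, "scores") <- scores
  attr(sk, "retained") <- retained
  sk
}
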