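#' PC-algorithm skeleton phase
#'
#' Estimates the undirected skeleton by iterative conditional-independence
#' testing. Starting from a complete graph, for orders \eqn{\ell = 0, 1,
#' \ldots} every ordered pair of adjacent nodes \eqn{(X_i, X_j)} is tested
#' against conditioning sets \eqn{Y} of size \eqn{\ell} drawn from the
#' current neighbours of \eqn{X_i} (excluding \eqn{X_j}), enumerated in
#' lexicographic order of the variable ordering; the edge is deleted on the
#' first set found that renders the pair independent. Adjacency updates are
#' immediate (classic PC, not PC-stable), so with imperfect tests the result
#' depends on `ordering` -- the property PriorPC exploits.
#'
#' The search stops early once no adjacent pair has enough neighbours for the
#' next order, or after `config$max_order`.
#'
#' @param x Either an [expression_dataset()] (Gaussian partial-correlation
#'   tests, fast compiled path) or a CI callable `f(i, j, Y)` such as
#'   [dsep_oracle()] or [gaussian_ci_test()].
#' @param variables Character vector of variables (required for the callable
#'   form; ignored for datasets).
#' @param ordering Permutation of the variables (`order(V)`); default is the
#'   lexicographic ordering of the identifiers.
#' @param config A [ci_config()].
#' @return A [skeleton()] with attributes `n_tests` (CI-test count per order)
#'   and `sepsets` (named list: separation set recorded for each removed
#'   edge).
#' @examples
#' dag <- true_dag(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
#' sk <- pc_skeleton(dsep_oracle(dag), variables = dag$nodes)
#' sk$edges
#' @export
pc_skeleton <- function(x, variables = NULL, ordering = NULL,
                        config = ci_config()) {
  UseMethod("pc_skeleton")
}

check_ordering <- function(ordering, variables) {
  if (is.null(ordering)) {
    return(sort_c(variables))
  }
  ordering <- as.character(ordering)
  if (!setequal(ordering, variables) || length(ordering) != length(variables)) {
    stop("`ordering` must be a permutation of the variables")
  }
  ordering
}

#' @export
pc_skeleton.expression_dataset <- function(x, variables = NULL,
                                           ordering = NULL,
                                           config = ci_config()) {
  ordering <- check_ordering(ordering, x$variables)
  stats <- correlation_stats(x, shrinkage = config$shrinkage)
  run_pc_scan_fast(
    R = stats$R, n = stats$n, variables = x$variables,
    ordering = ordering, config = config, adj = NULL, min_order = 0L
  )
}

#' @export
pc_skeleton.function <- function(x, variables = NULL, ordering = NULL,
                                 config = ci_config()) {
  if (is.null(variables)) {
    variables <- attr(x, "variables")
    if (is.null(variables)) variables <- attr(x, "nodes")
  }
  if (is.null(variables)) {
    stop("`variables` is required when `x` is a CI callable")
  }
  ordering <- check_ordering(ordering, variables)
  run_pc_scan_generic(
    ci = x, variables = variables, ordering = ordering,
    config = config, adj = NULL, min_order = 0L
  )
}

# Shared driver: complete (or given) starting adjacency, orders
# min_order..max_order through the compiled scan.
run_pc_scan_fast <- function(R, n, variables, ordering, config, adj = NULL,
                             min_order = 0L) {
  p <- length(variables)
  if (is.null(adj)) {
    adj <- matrix(TRUE, p, p)
    diag(adj) <- FALSE
  }
  ord0 <- match(ordering, variables) - 1L
  n_tests <- integer(0)
  sepsets <- list()
  for (ell in seq.int(min_order, config$max_order)) {
    cand <- which(rowSums(adj) - 1L >= ell)
    if (!length(cand) || !any(adj[cand, , drop = FALSE])) break
    res <- pc_scan_order_cpp(R, as.integer(n), adj, as.integer(ell),
      config$t, ord0
    )
    adj <- res$adj
    n_tests <- c(n_tests, stats::setNames(as.integer(res$n_tests), ell))
    if (length(res$removed_i)) {
      rp <- canonical_pairs(variables[res$removed_i], variables[res$removed_j])
      keys <- pair_key(rp[, 1], rp[, 2])
      sep <- lapply(res$sepsets, function(s) variables[s])
      names(sep) <- keys
      sepsets <- c(sepsets, sep)
    }
  }
  finish_skeleton(adj, variables, n_tests, sepsets)
}

run_pc_scan_generic <- function(ci, variables, ordering, config, adj = NULL,
                                min_order = 0L) {
  p <- length(variables)
  if (is.null(adj)) {
    adj <- matrix(TRUE, p, p)
    diag(adj) <- FALSE
  }
  ord_idx <- match(ordering, variables)
  n_tests <- integer(0)
  sepsets <- list()
  for (ell in seq.int(min_order, config$max_order)) {
    cand <- which(rowSums(adj) - 1L >= ell)
    if (!length(cand) || !any(adj[cand, , drop = FALSE])) break
    tests <- 0L
    for (a in ord_idx) {
      for (b in ord_idx) {
        if (a == b || !adj[a, b]) next
        nbrs <- ord_idx[adj[a, ord_idx]]
        nbrs <- nbrs[nbrs != b]
        if (length(nbrs) < ell) next
        hit <- find_sepset_generic(
          ci, variables, a, b, nbrs, ell,
          config$t
        )
        tests <- tests + hit$n_tests
        if (!is.null(hit$sepset)) {
          adj[a, b] <- adj[b, a] <- FALSE
          rp <- canonical_pairs(variables[a], variables[b])
          sepsets[[pair_key(rp[1, 1], rp[1, 2])]] <- variables[hit$sepset]
        }
      }
    }
    n_tests <- c(n_tests, stats::setNames(tests, ell))
  }
  finish_skeleton(adj, variables, n_tests, sepsets)
}

# Enumerate size-ell subsets of nbrs (already in ordering order)
# lexicographically; return the first separating set, if any.
find_sepset_generic <- function(ci, variables, a, b, nbrs, ell, t) {
  tests <- 0L
  if (ell == 0L) {
    tests <- 1L
    if (isTRUE(ci(variables[a], variables[b], character(0)))) {
      return(list(sepset = integer(0), n_tests = tests))
    }
    return(list(sepset = NULL, n_tests = tests))
  }
  subs <- combn(seq_along(nbrs), ell)
  for (col in seq_len(ncol(subs))) {
    Y <- nbrs[subs[, col]]
    tests <- tests + 1L
    if (isTRUE(ci(variables[a], variables[b], variables[Y]))) {
      return(list(sepset = Y, n_tests = tests))
    }
  }
  list(sepset = NULL, n_tests = tests)
}

finish_skeleton <- function(adj, variables, n_tests, sepsets) {
  keep <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- cbind(variables[keep[, 1]], variables[keep[, 2]])
  sk <- skeleton(variables, edges)
  attr(sk, "n_tests") <- n_tests
  attr(sk, "sepsets") <- sepsets
  sk
}

#' PC-lite: correlation-seeded PC skeleton
#'
#' A baseline variant of PC for large networks: instead of running all
#' zero-order tests from the complete graph, the `n_keep` node pairs with the
#' highest absolute marginal correlation (ties broken lexicographically) form
#' the initial graph, and PC then runs from order 1 to `config$max_order` on
#' these edges only.
#'
#' @param data An [expression_dataset()].
#' @param n_keep Number of top-correlation edges to seed (>= 1). Values
#'   exceeding the pair count keep all pairs, with a warning.
#' @param ordering,config As in [pc_skeleton()].
#' @return A [skeleton()] (attributes as in [pc_skeleton()], plus
#'   `initial_edges`).
#' @export
pc_lite <- function(data, n_keep, ordering = NULL, config = ci_config()) {
  stopifnot(inherits(data, "expression_dataset"))
  if (n_keep < 1) stop("`n_keep` must be >= 1")
  ordering <- check_ordering(ordering, data$variables)
  stats <- correlation_stats(data, shrinkage = config$shrinkage)
  retained <- top_pairs_by_score(stats$C, data$variables, n_keep)
  adj <- edges_to_adj(retained, data$variables)
  sk <- run_pc_scan_fast(
    R = stats$R, n = stats$n, variables = data$variables,
    ordering = ordering, config = config, adj = adj, min_order = 1L
  )
  attr(sk, "initial_edges") <- retained
  sk
}

# Top-n_keep canonical pairs of a symmetric score matrix, descending score,
# ties lexicographic by pair.
top_pairs_by_score <- function(S, variables, n_keep) {
  p <- length(variables)
  ut <- which(upper.tri(S), arr.ind = TRUE)
  pairs <- canonical_pairs(variables[ut[, 1]], variables[ut[, 2]])
  score <- S[ut]
  o <- order(-score, xtfrm_c(pairs[, 1]), xtfrm_c(pairs[, 2]))
  n_pairs <- nrow(pairs)
  if (n_keep > n_pairs) {
    warning(
      "n_keep (", n_keep, ") exceeds the number of pairs (", n_pairs,
      "); keeping all pairs"
    )
    n_keep <- n_pairs
  }
  sel <- o[seq_len(n_keep)]
  data.frame(
    from = pairs[sel, 1], to = pairs[sel, 2], score = score[sel],
    stringsAsFactors = FALSE
  )
}

edges_to_adj <- function(edges, variables) {
  p <- length(variables)
  adj <- matrix(FALSE, p, p)
  if (NROW(edges)) {
    fi <- match(edges[["from"]], variables)
    ti <- match(edges[["to"]], variables)
    adj[cbind(fi, ti)] <- TRUE
    adj[cbind(ti, fi)] <- TRUE
  }
  adj
}
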