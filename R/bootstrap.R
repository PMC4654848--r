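#' Bootstrap consensus edge ranking
#'
#' Draws `K` bootstrap datasets (samples resampled with replacement,
#' original size), runs a skeleton-producing algorithm on each, and scores
#' every edge by its frequency of appearance in the `K` skeletons (an
#' integer in 0..K). Edges are ranked by frequency descending; ties are
#' broken lexicographically by canonical pair. Per-resample RNG streams are
#' derived from the master seed, so results are reproducible and independent
#' of execution order.
#'
#' @param data An [expression_dataset()].
#' @param algorithm A deterministic function `f(data)` returning a
#'   [skeleton()] (e.g. a wrapper around [pc_lite()] or
#'   [priorpc_skeleton()]).
#' @param K Number of bootstrap resamples (default 20).
#' @param seed Optional master seed.
#' @return A [ranked_edges()] object (edges with frequency >= 1), with
#'   attribute `K`.
#' @export
bootstrap_rank <- function(data, algorithm, K = 20L, seed = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  K <- as.integer(K)
  if (is.na(K) || K < 1) stop("`K` must be a positive integer")
  counts <- new.env(parent = emptyenv())
  for (k in seq_len(K)) {
    idx <- with_seed(
      if (is.null(seed)) NULL else derive_seed(seed, k),
      sample.int(data$n, data$n, replace = TRUE)
    )
    resample <- expression_dataset(
      data$values[, idx, drop = FALSE],
      variables = data$variables
    )
    sk <- tryCatch(algorithm(resample), error = function(e) {
      stop("algorithm failed on bootstrap resample ", k, ": ",
        conditionMessage(e),
        call. = FALSE
      )
    })
    if (!inherits(sk, "skeleton")) {
      stop("algorithm must return a skeleton")
    }
    for (key in skeleton_keys(sk)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    out <- ranked_edges(character(0), character(0), numeric(0))
  } else {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    from <- vapply(parts, `[[`, "", 1L)
    to <- vapply(parts, `[[`, "", 2L)
    freq <- vapply(keys, function(k) counts[[k]], 0L)
    out <- ranked_edges(from, to, freq)
  }
  attr(out, "K") <- K
  out
}

#' Nodes eligible for evaluation
#'
#' Evaluation is restricted to nodes linked to at least one other node in the
#' gold standard; pairs touching isolated gold nodes are never counted.
#'
#' @param gold A [gold_standard()].
#' @return Character vector of nodes with gold degree >= 1.
#' @export
restrict_nodes <- function(gold) {
  stopifnot(inherits(gold, "gold_standard"))
  nodes <- unique(c(gold$edges))
  if (!length(nodes)) stop("gold standard has no edges")
  sort_c(nodes)
}

# Shared setup: scores and labels over all pairs within eval_nodes (or an
# explicit pair subset). Unranked pairs form a single bottom tie with score 0.
eval_scores <- function(ranking, gold, eval_nodes = NULL, pairs = NULL) {
  stopifnot(inherits(gold, "gold_standard"))
  if (is.null(pairs)) {
    if (is.null(eval_nodes)) eval_nodes <- restrict_nodes(gold)
    pairs <- all_pairs(eval_nodes)
  } else {
    pairs <- canonical_pairs(pairs[, 1], pairs[, 2])
  }
  if (!nrow(pairs)) stop("fewer than two evaluation nodes")
  keys <- pair_key(pairs[, 1], pairs[, 2])
  scores <- numeric(nrow(pairs))
  if (NROW(ranking)) {
    rk <- pair_key(ranking$from, ranking$to)
    hit <- match(keys, rk)
    scores[!is.na(hit)] <- ranking$score[hit[!is.na(hit)]]
  }
  labels <- keys %in% skeleton_keys(gold)
  list(scores = scores, labels = labels)
}

#' Area under the ROC curve of an edge ranking
#'
#' Rank-based AUROC over all node pairs within the evaluation node set, with
#' gold-standard edges as positives. Pairs absent from the ranking are
#' appended as a single bottom tie (score 0); tied scores are handled by the
#' mid-rank convention, so the result equals the probability that a random
#' positive outranks a random negative (ties counting one half).
#'
#' @param ranking A [ranked_edges()] object (or data frame with `from`, `to`,
#'   `score`).
#' @param gold A [gold_standard()].
#' @param eval_nodes Node subset to evaluate over; default
#'   [restrict_nodes()] of the gold standard.
#' @param pairs Optional explicit two-column matrix of node pairs to evaluate
#'   over (e.g. only the pairs without informative priors), overriding
#'   `eval_nodes`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(ranking, gold, eval_nodes = NULL, pairs = NULL) {
  ev <- eval_scores(ranking, gold, eval_nodes, pairs)
  P <- sum(ev$labels)
  N <- sum(!ev$labels)
  if (P == 0 || N == 0) {
    stop("AUROC undefined: need at least one positive and one negative pair")
  }
  r <- rank(ev$scores, ties.method = "average")
  (sum(r[ev$labels]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve of an edge ranking
#'
#' Non-interpolated step-wise area: the PR curve is stepped over the distinct
#' score thresholds (all pairs sharing a score enter together) and the area
#' is \eqn{\sum_k (R_k - R_{k-1}) P_k}, the convention used in DREAM-style
#' network evaluations.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(ranking, gold, eval_nodes = NULL, pairs = NULL) {
  ev <- eval_scores(ranking, gold, eval_nodes, pairs)
  P <- sum(ev$labels)
  if (P == 0) {
    stop("AUPRC undefined: no positive pairs")
  }
  o <- order(ev$scores, decreasing = TRUE)
  s <- ev$scores[o]
  y <- ev$labels[o]
  # indices where a distinct-score block ends
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]
  npred <- ends
  prec <- tp / npred
  rec <- tp / P
  sum((rec - c(0, rec[-length(rec)])) * prec)
}
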