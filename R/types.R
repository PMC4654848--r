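#' Expression dataset container
#'
#' Holds a genes-by-samples numeric matrix together with the canonical
#' variable ordering (the row order of the source file). Expression values
#' are in arbitrary units; all downstream statistics are scale-invariant.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are used as gene identifiers when `variables` is missing.
#' @param variables Character vector of unique gene identifiers, one per row.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (|V| x n matrix with rownames), `variables`, and `n`.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
#' d <- expression_dataset(m)
#' d$n
#' @export
expression_dataset <- function(values, variables = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(variables)) {
    stop("gene identifiers are required (row names or `variables`)")
  }
  variables <- as.character(variables)
  if (length(variables) != nrow(values)) {
    stop("`variables` must have one entry per row of `values`")
  }
  if (anyDuplicated(variables)) {
    dup <- unique(variables[duplicated(variables)])
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values")
  }
  if (nrow(values) < 2) {
    stop("at least 2 genes are required")
  }
  if (ncol(values) < 1) {
    stop("at least 1 sample is required")
  }
  rownames(values) <- variables
  structure(
    list(values = values, variables = variables, n = ncol(values)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(
    "<expression_dataset> ", length(x$variables), " genes x ",
    x$n, " samples\n",
    sep = ""
  )
  invisible(x)
}

#' Prior belief matrix
#'
#' A symmetric matrix of per-pair beliefs \eqn{b_{ij} \in [0,1]} about edge
#' existence: 0 is the strongest belief in absence, 1 the strongest belief in
#' presence, and 0.5 is non-informative. The diagonal is unused and kept at
#' 0.5.
#'
#' @param beliefs Square numeric matrix with dimnames naming the variables,
#'   or missing to build an all-0.5 matrix from `variables`.
#' @param variables Character vector of variable identifiers (required when
#'   `beliefs` is missing; otherwise taken from dimnames).
#' @return An object of class `prior_matrix` (a named numeric matrix).
#' @examples
#' B <- prior_matrix(variables = c("g1", "g2", "g3"))
#' B["g1", "g2"]
#' @export
prior_matrix <- function(beliefs = NULL, variables = NULL) {
  if (is.null(beliefs)) {
    if (is.null(variables)) {
      stop("either `beliefs` or `variables` must be given")
    }
    variables <- as.character(variables)
    p <- length(variables)
    beliefs <- matrix(0.5, p, p, dimnames = list(variables, variables))
  } else {
    beliefs <- as.matrix(beliefs)
    if (is.null(variables)) {
      variables <- rownames(beliefs)
    }
    if (is.null(variables)) {
      stop("prior matrix needs variable names (dimnames or `variables`)")
    }
    dimnames(beliefs) <- list(variables, variables)
  }
  validate_prior(beliefs)
  structure(beliefs, class = c("prior_matrix", "matrix"))
}

validate_prior <- function(beliefs) {
  if (nrow(beliefs) != ncol(beliefs)) {
    stop("prior matrix must be square")
  }
  if (anyNA(beliefs)) {
    stop("prior matrix contains missing values")
  }
  if (any(beliefs < 0 | beliefs > 1)) {
    stop("prior beliefs must lie in [0, 1]")
  }
  if (max(abs(beliefs - t(beliefs))) > 1e-9) {
    stop("prior matrix must be symmetric (|b_ij - b_ji| <= 1e-9)")
  }
  invisible(beliefs)
}

#' Undirected network skeleton
#'
#' The output structure of the PC-family algorithms: an undirected graph over
#' the gene set, stored as canonical node pairs (lexicographically smaller
#' identifier first), without self-loops or duplicates.
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Two-column character matrix or data frame of node pairs
#'   (direction, if any, is dropped).
#' @return An object of class `skeleton`: list with `nodes` and `edges`
#'   (canonical two-column character matrix, lexicographically sorted rows).
#' @examples
#' skeleton(c("a", "b", "c"), cbind(c("b", "c"), c("a", "b")))
#' @export
skeleton <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers")
  }
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- cbind(from = character(0), to = character(0))
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2) {
      stop("edges must have two columns")
    }
    self <- edges[, 1] == edges[, 2]
    if (any(self)) {
      warning(sum(self), " self-loop(s) dropped")
      edges <- edges[!self, , drop = FALSE]
    }
    edges <- canonical_pairs(edges[, 1], edges[, 2])
    edges <- edges[!duplicated(pair_key(edges[, 1], edges[, 2])), ,
      drop = FALSE
    ]
    edges <- edges[order_pairs(edges[, 1], edges[, 2]), , drop = FALSE]
    missing <- setdiff(unique(c(edges)), nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not in node set: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(
    "<", class(x)[1], "> ", length(x$nodes), " nodes, ",
    nrow(x$edges), " undirected edges\n",
    sep = ""
  )
  invisible(x)
}

#' Gold-standard network
#'
#' A reference edge set used for evaluation and synthetic-prior construction.
#' Directed reference networks are collapsed to their skeleton (directions
#' dropped, duplicates merged), since only undirected structure is assessed.
#'
#' @inheritParams skeleton
#' @return An object of class `gold_standard` (also a `skeleton`).
#' @export
gold_standard <- function(nodes, edges = NULL) {
  out <- skeleton(nodes, edges)
  class(out) <- c("gold_standard", class(out))
  out
}

#' Ranked edge list
#'
#' Edges ordered by a confidence score, typically the bootstrap appearance
#' frequency (an integer in 0..K). Sorted by score descending with ties
#' broken lexicographically by canonical pair; no duplicate pairs.
#'
#' @param from,to Character vectors of node identifiers.
#' @param score Numeric scores (higher = more confident).
#' @return An object of class `ranked_edges`: a data frame with columns
#'   `from`, `to`, `score`, in rank order.
#' @export
ranked_edges <- function(from, to, score) {
  pairs <- canonical_pairs(from, to)
  score <- as.numeric(score)
  if (length(score) != nrow(pairs)) {
    stop("`score` must match the number of edges")
  }
  if (anyDuplicated(pair_key(pairs[, 1], pairs[, 2]))) {
    stop("duplicate edge in ranking")
  }
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("self-loop in ranking")
  }
  o <- order(-score, xtfrm_c(pairs[, 1]), xtfrm_c(pairs[, 2]))
  out <- data.frame(
    from = pairs[o, 1], to = pairs[o, 2], score = score[o],
    stringsAsFactors = FALSE
  )
  class(out) <- c("ranked_edges", class(out))
  out
}

#' Directed acyclic graph (ground truth)
#'
#' The generating structure used by the d-separation oracle and the
#' synthetic-data simulator. Acyclicity is checked at construction.
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Two-column character matrix of directed edges (parent,
#'   child).
#' @return An object of class `true_dag`: list with `nodes`, `edges`, and
#'   `order` (a topological order).
#' @export
true_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers")
  }
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- cbind(from = character(0), to = character(0))
  } else {
    edges <- as.matrix(edges)
    colnames(edges) <- c("from", "to")[seq_len(min(2, ncol(edges)))]
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loop in DAG edge list")
    }
    edges <- edges[!duplicated(pair_key(edges[, 1], edges[, 2])), ,
      drop = FALSE
    ]
  }
  topo <- topological_order(nodes, edges)
  if (is.null(topo)) {
    stop("edge list contains a cycle; not a DAG")
  }
  structure(
    list(nodes = nodes, edges = edges, order = topo),
    class = "true_dag"
  )
}

#' @export
print.true_dag <- function(x, ...) {
  cat(
    "<true_dag> ", length(x$nodes), " nodes, ", nrow(x$edges),
    " directed edges\n",
    sep = ""
  )
  invisible(x)
}

# Kahn's algorithm; NULL if a cycle exists.
topological_order <- function(nodes, edges) {
  p <- length(nodes)
  idx <- stats::setNames(seq_len(p), nodes)
  indeg <- integer(p)
  children <- vector("list", p)
  if (NROW(edges)) {
    fi <- idx[edges[, 1]]
    ti <- idx[edges[, 2]]
    if (anyNA(fi) || anyNA(ti)) {
      stop("edge endpoint(s) not in node set")
    }
    for (k in seq_along(fi)) {
      children[[fi[k]]] <- c(children[[fi[k]]], ti[k])
      indeg[ti[k]] <- indeg[ti[k]] + 1L
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != p) {
    return(NULL)
  }
  nodes[out]
}

#' Undirected skeleton of a DAG
#'
#' @param dag A [true_dag()].
#' @return A [gold_standard()] with the DAG's edges, directions dropped.
#' @export
dag_skeleton <- function(dag) {
  stopifnot(inherits(dag, "true_dag"))
  gold_standard(dag$nodes, dag$edges)
}

# Edge keys of a skeleton-like object.
skeleton_keys <- function(x) {
  pair_key(x$edges[, 1], x$edges[, 2])
}
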