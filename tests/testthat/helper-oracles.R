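# Independent reference implementations used to cross-check the package:
# these deliberately take the slow, textbook route.

# Partial correlation by the recursion formula, reducing the conditioning
# set one variable at a time.
pcor_recursive <- function(X, i, j, Y) {
  # X: samples x variables matrix with colnames
  if (!length(Y)) {
    return(cor(X[, i], X[, j]))
  }
  z <- Y[length(Y)]
  rest <- Y[-length(Y)]
  rij <- pcor_recursive(X, i, j, rest)
  riz <- pcor_recursive(X, i, z, rest)
  rjz <- pcor_recursive(X, j, z, rest)
  (rij - riz * rjz) / sqrt((1 - riz^2) * (1 - rjz^2))
}

# d-separation by exhaustive enumeration of simple paths and the
# path-blocking rules.
dsep_bruteforce <- function(dag, i, j, Y = character()) {
  nodes <- dag$nodes
  edges <- dag$edges
  p <- length(nodes)
  und <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  dir <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    und[edges] <- TRUE
    und[edges[, c(2, 1), drop = FALSE]] <- TRUE
    dir[edges] <- TRUE
  }
  # descendants (including self) per node
  desc <- lapply(nodes, function(v) {
    seen <- v
    frontier <- v
    while (length(frontier)) {
      nxt <- nodes[colSums(dir[frontier, , drop = FALSE]) > 0]
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  })
  names(desc) <- nodes

  path_active <- function(path) {
    if (length(path) <= 2) {
      return(TRUE)
    }
    for (k in 2:(length(path) - 1)) {
      a <- path[k - 1]
      v <- path[k]
      b <- path[k + 1]
      collider <- dir[a, v] && dir[b, v]
      if (collider) {
        if (!any(desc[[v]] %in% Y)) {
          return(FALSE)
        }
      } else {
        if (v %in% Y) {
          return(FALSE)
        }
      }
    }
    TRUE
  }

  found_active <- FALSE
  walk <- function(path) {
    if (found_active) {
      return()
    }
    v <- path[length(path)]
    if (v == j) {
      if (path_active(path)) found_active <<- TRUE
      return()
    }
    for (w in nodes[und[v, ]]) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(i)
  !found_active
}

# Random small DAG over given node names with at most max_deg undirected
# degree, as a plain structure for oracle tests.
random_small_dag <- function(n_nodes, n_edges, seed, max_deg = Inf) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  repeat {
    topo <- sample(nodes)
    pairs <- t(combn(seq_len(n_nodes), 2))
    sel <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
    edges <- cbind(topo[pairs[sel, 1]], topo[pairs[sel, 2]])
    deg <- table(factor(c(edges), levels = nodes))
    if (all(deg <= max_deg)) {
      return(true_dag(nodes, edges))
    }
  }
}

# Tiny deterministic expression fixture.
toy_dataset <- function(seed = 1, p = 5, n = 40) {
  set.seed(seed)
  m <- matrix(rnorm(p * n), nrow = p,
    dimnames = list(sprintf("g%d", seq_len(p)), NULL)
  )
  expression_dataset(m)
}

# Seed an expression locally without touching the ambient RNG stream.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

skeleton_edge_keys <- function(sk) {
  paste(sk$edges[, 1], sk$edges[, 2], sep = "~")
}
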