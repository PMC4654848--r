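#' Exact d-separation oracle
#'
#' Builds a "perfect CI test" from a known DAG: the returned callable answers
#' queries `(i, j, Y)` with `TRUE` exactly when the DAG d-separates i and j
#' given Y, i.e. when every path between them is blocked (a non-collider on
#' the path is in Y, or a collider has no descendant in Y). Implemented with
#' the reachability (Bayes-ball) algorithm, linear in the graph size per
#' query.
#'
#' @param dag A [true_dag()].
#' @return A function `(i, j, Y)` of class `dsep_ci` returning a logical.
#' @examples
#' dag <- true_dag(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
#' ci <- dsep_oracle(dag)
#' ci("A", "C", "B") # TRUE: chain blocked by its middle node
#' ci("A", "C") # FALSE: marginally dependent
#' @export
dsep_oracle <- function(dag) {
  stopifnot(inherits(dag, "true_dag"))
  p <- length(dag$nodes)
  idx <- stats::setNames(seq_len(p), dag$nodes)
  parents <- vector("list", p)
  children <- vector("list", p)
  if (nrow(dag$edges)) {
    fi <- unname(idx[dag$edges[, 1]])
    ti <- unname(idx[dag$edges[, 2]])
    for (k in seq_along(fi)) {
      children[[fi[k]]] <- c(children[[fi[k]]], ti[k])
      parents[[ti[k]]] <- c(parents[[ti[k]]], fi[k])
    }
  }

  ancestors_of <- function(zz) {
    anc <- logical(p)
    stack <- zz
    anc[zz] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (u in parents[[v]]) {
        if (!anc[u]) {
          anc[u] <- TRUE
          stack <- c(stack, u)
        }
      }
    }
    anc
  }

  f <- function(i, j, Y = character()) {
    Y <- as.character(Y)
    q <- c(i, j, Y)
    if (!all(q %in% dag$nodes)) {
      stop(
        "unknown variable(s): ",
        paste(setdiff(q, dag$nodes), collapse = ", ")
      )
    }
    x <- idx[[i]]
    y <- idx[[j]]
    if (x == y) stop("`i` and `j` must be distinct")
    zz <- unname(idx[Y])
    if (x %in% zz || y %in% zz) stop("`Y` must exclude i and j")
    inz <- logical(p)
    inz[zz] <- TRUE
    anz <- ancestors_of(zz) # in Z or with a descendant in Z

    # reachability over (node, direction) states; direction 1 = arrived from
    # a child (moving up), 2 = arrived from a parent (moving down)
    seen <- matrix(FALSE, p, 2)
    stack_v <- x
    stack_d <- 1L
    while (length(stack_v)) {
      k <- length(stack_v)
      v <- stack_v[k]
      d <- stack_d[k]
      stack_v <- stack_v[-k]
      stack_d <- stack_d[-k]
      if (seen[v, d]) next
      seen[v, d] <- TRUE
      if (v == y && !inz[v]) {
        return(FALSE) # active trail reaches j: dependent
      }
      if (d == 1L) {
        if (!inz[v]) {
          for (u in parents[[v]]) {
            stack_v <- c(stack_v, u)
            stack_d <- c(stack_d, 1L)
          }
          for (u in children[[v]]) {
            stack_v <- c(stack_v, u)
            stack_d <- c(stack_d, 2L)
          }
        }
      } else {
        if (!inz[v]) {
          for (u in children[[v]]) {
            stack_v <- c(stack_v, u)
            stack_d <- c(stack_d, 2L)
          }
        }
        if (anz[v]) { # collider with self or descendant in Z: trail continues up
          for (u in parents[[v]]) {
            stack_v <- c(stack_v, u)
            stack_d <- c(stack_d, 1L)
          }
        }
      }
    }
    TRUE
  }
  structure(f, class = c("dsep_ci", "function"), nodes = dag$nodes)
}
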