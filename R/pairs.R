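#' Canonical undirected node pairs
#'
#' An undirected edge between two gene identifiers is stored canonically with
#' the lexicographically smaller identifier first. This makes edge sets
#' comparable across modules and gives the deterministic tie-breaking used
#' when ranking edges.
#'
#' @param a,b Character vectors of node identifiers (recycled to common
#'   length).
#' @return A two-column character matrix with columns `from`, `to`, where
#'   `from <= to` lexicographically in the C locale.
#' @examples
#' canonical_pairs(c("g2", "g1"), c("g1", "g2"))
#' @export
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  swap <- cmp_gt(a, b)
  from <- ifelse(swap, b, a)
  to <- ifelse(swap, a, b)
  cbind(from = from, to = to)
}

# Byte-wise (C locale) string comparison a > b, so canonicalization does not
# depend on the session's collation locale.
cmp_gt <- function(a, b) {
  n <- length(a)
  if (n == 0) {
    return(logical(0))
  }
  r <- rank(xtfrm_c(c(a, b)), ties.method = "min")
  r[seq_len(n)] > r[n + seq_len(n)]
}

# Locale-independent sort keys via radix order.
xtfrm_c <- function(x) {
  o <- order(x, method = "radix")
  k <- integer(length(x))
  k[o] <- seq_along(x)
  # equal strings must map to equal keys
  d <- !duplicated(x[o])
  kk <- cumsum(d)
  k2 <- integer(length(x))
  k2[o] <- kk
  k2
}

# Order indices of a from/to pair table lexicographically (byte order).
order_pairs <- function(from, to) {
  order(from, to, method = "radix")
}

pair_key <- function(from, to) paste(from, to, sep = "\r")

# All canonical pairs over a node set, in lexicographic order.
all_pairs <- function(nodes) {
  nodes <- sort_c(nodes)
  p <- length(nodes)
  if (p < 2) {
    return(cbind(from = character(0), to = character(0)))
  }
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cbind(from = nodes[idx[, 1]], to = nodes[idx[, 2]])
}

sort_c <- function(x) {
  sort(x, method = "radix")
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. With seed = NULL the expression uses (and
# advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seeds below 2^31, so one master seed fans out to
# independent, order-free component streams.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + as.numeric(offset) * 16807) %% 2147483629 + 1
}
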