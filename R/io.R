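#' Read an expression matrix
#'
#' Reads a tab-separated genes-by-samples matrix: first column gene
#' identifiers, remaining columns numeric expression values, with an optional
#' header row. The file row order becomes the canonical variable ordering.
#'
#' @param path Path to a TSV file.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, "\t", fixed = TRUE)[[1]]
  # header row: every cell after the gene-id column is non-numeric
  has_header <- length(cells) > 1 &&
    all(is.na(suppressWarnings(as.numeric(cells[-1]))))
  tab <- read.table(path,
    sep = "\t", header = has_header, check.names = FALSE,
    colClasses = "character", quote = "", comment.char = ""
  )
  if (ncol(tab) < 2) {
    stop("expression file needs a gene-id column plus >= 1 sample column")
  }
  ids <- tab[[1]]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric value '%s' at gene '%s' (row %d), sample column %d",
      raw[bad[1], bad[2]], ids[bad[1]], bad[1], bad[2]
    ))
  }
  colnames(vals) <- colnames(tab)[-1]
  expression_dataset(vals, variables = ids)
}

#' Write an expression matrix
#'
#' @param data An [expression_dataset()].
#' @param path Output path (tab-separated, `.` decimal, header row of sample
#'   names).
#' @export
write_expression <- function(data, path) {
  stopifnot(inherits(data, "expression_dataset"))
  vals <- data$values
  if (is.null(colnames(vals))) {
    colnames(vals) <- paste0("S", seq_len(ncol(vals)))
  }
  tab <- data.frame(gene = data$variables, vals, check.names = FALSE)
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Reads a DREAM-style edge list: three tab-separated columns (source,
#' target, indicator in \{0,1\}) or two columns (source, target). Rows with
#' indicator 0 are ignored; self-loops are skipped with a warning; directed
#' pairs are collapsed to canonical undirected pairs and deduplicated.
#'
#' @param path Path to the edge-list file.
#' @param nodes Optional character vector of the full node set (isolated
#'   nodes cannot be recovered from an edge list alone). Defaults to the
#'   nodes appearing in the file.
#' @return A [gold_standard()].
#' @export
read_edge_list <- function(path, nodes = NULL) {
  tab <- tryCatch(
    read.table(path,
      sep = "\t", header = FALSE, colClasses = "character",
      quote = "", comment.char = ""
    ),
    error = function(e) NULL
  )
  if (is.null(tab)) { # empty file
    if (is.null(nodes)) stop("empty edge list and no `nodes` given")
    return(gold_standard(nodes))
  }
  if (!ncol(tab) %in% c(2L, 3L)) {
    stop("edge list must have 2 or 3 columns, found ", ncol(tab))
  }
  if (ncol(tab) == 3L) {
    ind <- suppressWarnings(as.numeric(tab[[3]]))
    if (anyNA(ind) || !all(ind %in% c(0, 1))) {
      stop("third column must be a 0/1 indicator")
    }
    tab <- tab[ind == 1, , drop = FALSE]
  }
  from <- tab[[1]]
  to <- tab[[2]]
  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-loop row(s) skipped")
    from <- from[!self]
    to <- to[!self]
  }
  if (is.null(nodes)) {
    nodes <- sort_c(unique(c(from, to)))
  }
  gold_standard(nodes, cbind(from, to))
}

#' Write a gold-standard / skeleton edge list
#'
#' Three-column DREAM-style output: source, target, indicator 1.
#'
#' @param x A `skeleton` or `gold_standard`.
#' @param path Output path.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "skeleton"))
  tab <- data.frame(
    from = x$edges[, 1], to = x$edges[, 2],
    present = rep(1L, nrow(x$edges))
  )
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  invisible(path)
}

#' Read a prior belief matrix
#'
#' Accepts either a full square matrix file (tab-separated, row and column
#' names) or a 3-column list (node, node, belief). Pairs not listed default
#' to the non-informative belief 0.5.
#'
#' @param path Path to the prior file.
#' @param variables Ordered character vector of the dataset's variables; the
#'   returned matrix is aligned to this ordering.
#' @return A [prior_matrix()].
#' @export
read_prior_matrix <- function(path, variables) {
  variables <- as.character(variables)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    return(prior_matrix(variables = variables))
  }
  cells <- strsplit(first, "\t", fixed = TRUE)[[1]]
  # a full-matrix file starts with a header row of variable names
  is_matrix <- length(cells) >= 2 && all(cells[-1] %in% variables) &&
    sum(cells[-1] %in% variables) >= 2
  if (is_matrix) {
    # full square matrix with row/col names
    tab <- read.table(path,
      sep = "\t", header = TRUE, row.names = 1,
      check.names = FALSE, quote = "", comment.char = ""
    )
    m <- as.matrix(tab)
    if (!setequal(rownames(m), variables) || !setequal(colnames(m), variables)) {
      stop("prior matrix variables do not match the dataset's")
    }
    m <- m[variables, variables]
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9) {
      stop("asymmetric prior matrix (|b_ij - b_ji| > 1e-9)")
    }
    m <- (m + t(m)) / 2
    diag(m) <- 0.5
    return(prior_matrix(m))
  }
  tab <- tryCatch(
    read.table(path,
      sep = "\t", header = FALSE, colClasses = "character",
      quote = "", comment.char = ""
    ),
    error = function(e) NULL
  )
  B <- prior_matrix(variables = variables)
  if (is.null(tab)) {
    return(B)
  }
  if (ncol(tab) != 3L) {
    stop("3-column (node, node, belief) prior list expected, found ", ncol(tab))
  }
  miss <- setdiff(unique(c(tab[[1]], tab[[2]])), variables)
  if (length(miss)) {
    stop("prior refers to unknown variable(s): ", paste(miss, collapse = ", "))
  }
  b <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(b)) {
    stop("non-numeric belief value in prior list")
  }
  if (any(b < 0 | b > 1)) {
    stop("prior beliefs must lie in [0, 1]")
  }
  for (k in seq_along(b)) {
    B[tab[k, 1], tab[k, 2]] <- b[k]
    B[tab[k, 2], tab[k, 1]] <- b[k]
  }
  diag(B) <- 0.5
  prior_matrix(unclass(B))
}

#' Write a prior matrix as a 3-column list
#'
#' Only informative entries (belief != 0.5) are written; readers restore the
#' 0.5 default for unlisted pairs.
#'
#' @param B A [prior_matrix()].
#' @param path Output path.
#' @export
write_prior_matrix <- function(B, path) {
  stopifnot(inherits(B, "prior_matrix"))
  vars <- rownames(B)
  pairs <- all_pairs(vars)
  b <- B[cbind(pairs[, 1], pairs[, 2])]
  keep <- b != 0.5
  tab <- data.frame(
    from = pairs[keep, 1], to = pairs[keep, 2],
    belief = format(b[keep], digits = 17)
  )
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  invisible(path)
}

#' Write a ranked edge list
#'
#' Three-column tab-separated output (node, node, score), one row per edge in
#' rank order; directly loadable as a Cytoscape edge table.
#'
#' @param ranking A [ranked_edges()] object.
#' @param path Output path.
#' @export
write_ranked_edges <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranked_edges"))
  tab <- data.frame(ranking$from, ranking$to,
    format(ranking$score, digits = 15, trim = TRUE, scientific = FALSE)
  )
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  invisible(path)
}

#' Read a ranked edge list
#'
#' @param path Path written by [write_ranked_edges()].
#' @return A [ranked_edges()] object.
#' @export
read_ranked_edges <- function(path) {
  tab <- tryCatch(
    read.table(path,
      sep = "\t", header = FALSE, colClasses = "character",
      quote = "", comment.char = ""
    ),
    error = function(e) NULL
  )
  if (is.null(tab)) {
    return(ranked_edges(character(0), character(0), numeric(0)))
  }
  if (ncol(tab) != 3L) {
    stop("ranked edge list must have 3 columns, found ", ncol(tab))
  }
  ranked_edges(tab[[1]], tab[[2]], as.numeric(tab[[3]]))
}
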