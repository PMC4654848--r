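#' Conditional-independence test configuration
#'
#' Defaults follow the standard operating point for Gaussian
#' partial-correlation tests in sparse network reconstruction: a decision
#' threshold `t = 0.1` on the scaled Fisher z statistic and a maximum
#' conditioning-set size of 5.
#'
#' @param t Decision threshold (> 0): the pair is declared conditionally
#'   independent when `|z| * sqrt(n - |Y| - 3) <= t`. Equivalent to a
#'   two-sided significance level via [beta_to_threshold()].
#' @param max_order Maximum conditioning-set size (integer >= 0).
#' @param shrinkage Logical; if `TRUE`, partial correlations are computed
#'   from a shrunken correlation matrix (see [correlation_stats()]).
#' @return A list of class `ci_config`.
#' @export
ci_config <- function(t = 0.1, max_order = 5L, shrinkage = FALSE) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0) {
    stop("`t` must be a positive number")
  }
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 0) {
    stop("`max_order` must be a non-negative integer")
  }
  structure(
    list(t = t, max_order = max_order, shrinkage = isTRUE(shrinkage)),
    class = "ci_config"
  )
}

#' Convert a two-sided significance level to a decision threshold
#'
#' The Fisher z test rejects zero partial correlation at level `beta` when
#' the scaled statistic exceeds \eqn{\Phi^{-1}(1 - \beta/2)}; that quantile
#' is the threshold `t` used by [ci_config()].
#'
#' @param beta Two-sided significance level in (0, 1).
#' @return The threshold `t`.
#' @examples
#' beta_to_threshold(0.01)
#' @export
beta_to_threshold <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) {
    stop("`beta` must lie in (0, 1)")
  }
  qnorm(1 - beta / 2)
}

#' Correlation matrix with per-gene background statistics
#'
#' Computes the Pearson correlation matrix of the dataset, stores its
#' absolute values `C`, and summarizes each gene's correlation background:
#' `mu[i]` and `sigma[i]` are the mean and standard deviation of the
#' off-diagonal entries of row i of `C` (the absolute correlations between
#' gene i and all other genes). These backgrounds drive the CLR-style data
#' score of PriorPC.
#'
#' @param data An [expression_dataset()] with `n >= 3` samples.
#' @param shrinkage Logical; if `TRUE` the signed correlation matrix is
#'   shrunk towards the identity with a Ledoit-Wolf-style intensity estimated
#'   from the data (computed once per dataset) before absolute values are
#'   taken, which also guarantees invertible submatrices in the
#'   partial-correlation tests.
#' @return A list of class `correlation_stats` with elements `R` (signed
#'   correlations), `C` (absolute correlations), `mu`, `sigma`, `n`,
#'   `variables`, `lambda` (shrinkage intensity used, 0 if none).
#' @export
correlation_stats <- function(data, shrinkage = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  if (data$n < 3) {
    stop("at least 3 samples are required for correlation estimates")
  }
  X <- t(data$values) # n x p
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    stop(
      "zero-variance gene(s): ",
      paste(data$variables[v == 0], collapse = ", ")
    )
  }
  R <- cor(X)
  lambda <- 0
  if (isTRUE(shrinkage)) {
    lambda <- shrinkage_intensity(X, R)
    R <- (1 - lambda) * R
    diag(R) <- 1
  }
  C <- abs(R)
  diag(C) <- 1
  p <- ncol(C)
  mu <- (rowSums(C) - 1) / (p - 1)
  # off-diagonal sd per row
  sq <- (rowSums(C^2) - 1) / (p - 1)
  sigma <- sqrt(pmax(0, (sq - mu^2) * (p - 1) / (p - 2)))
  structure(
    list(
      R = R, C = C, mu = mu, sigma = sigma, n = data$n,
      variables = data$variables, lambda = lambda
    ),
    class = "correlation_stats"
  )
}

# Schaefer-Strimmer estimate of the optimal intensity for shrinking
# off-diagonal correlations towards zero: lambda* = sum Var(r_ij) / sum r_ij^2.
shrinkage_intensity <- function(X, R) {
  n <- nrow(X)
  Xs <- scale(X) # standardized columns
  w_bar <- R * (n - 1) / n
  num <- 0
  p <- ncol(X)
  # var_hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2,
  # with w_kij = xs_ki * xs_kj
  sum_w2 <- crossprod(Xs^2) # sum_k w_kij^2
  var_r <- (sum_w2 - n * w_bar^2) * n / (n - 1)^3
  off <- upper.tri(R)
  num <- sum(var_r[off])
  den <- sum(R[off]^2)
  if (den <= 0) {
    return(0)
  }
  min(1, max(0, num / den))
}

#' Fisher z-transform
#'
#' \eqn{z(r) = \frac{1}{2}\log\frac{1+r}{1-r}}; an odd function of the
#' (partial) correlation, variance-stabilizing under Gaussianity.
#'
#' @param r Correlation value(s) with `|r| < 1`.
#' @return Transformed value(s).
#' @examples
#' fisher_z(0.5) # log(3) / 2
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Scaled Fisher z test statistic
#'
#' The statistic \eqn{|z(r)| \sqrt{n - k - 3}} compared against the decision
#' threshold `t`: values at or below `t` are consistent with zero partial
#' correlation of order `k`.
#'
#' @param r (Partial) correlation with `|r| < 1`.
#' @param n Sample count.
#' @param k Conditioning-set size (order of the test).
#' @return Non-negative statistic.
#' @examples
#' ci_statistic(0.5, n = 50, k = 0)
#' @export
ci_statistic <- function(r, n, k) {
  df <- n - k - 3
  if (df < 1) {
    stop("insufficient samples for order ", k, " (need n - k - 3 >= 1)")
  }
  abs(fisher_z(r)) * sqrt(df)
}

#' Sample partial correlation
#'
#' Computes \eqn{cor(X_i, X_j | Y)} by inverting the covariance submatrix
#' over \eqn{\{i, j\} \cup Y}: with \eqn{P} the inverse,
#' \eqn{-P_{ij} / \sqrt{P_{ii} P_{jj}}}. With an empty conditioning set this
#' reduces exactly to the Pearson correlation.
#'
#' @param data An [expression_dataset()].
#' @param i,j Variable identifiers (distinct).
#' @param Y Character vector of conditioning variables (excluding `i`, `j`).
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(data, i, j, Y = character()) {
  stopifnot(inherits(data, "expression_dataset"))
  Y <- as.character(Y)
  if (i == j) stop("`i` and `j` must be distinct")
  if (i %in% Y || j %in% Y) stop("`Y` must exclude i and j")
  vars <- c(i, j, Y)
  miss <- setdiff(vars, data$variables)
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  if (data$n - length(Y) - 3 < 1) {
    stop("insufficient samples for conditioning size ", length(Y))
  }
  if (!length(Y)) {
    return(cor(data$values[i, ], data$values[j, ]))
  }
  S <- cov(t(data$values[vars, , drop = FALSE]))
  P <- tryCatch(solve(S), error = function(e) {
    stop(
      "singular covariance submatrix for (", i, ", ", j,
      " | ...); consider ci_config(shrinkage = TRUE)"
    )
  })
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  max(-1, min(1, r))
}

#' Gaussian conditional-independence decision
#'
#' Declares \eqn{(X_i \perp X_j | Y)} when the scaled Fisher z statistic of
#' the sample partial correlation does not exceed `config$t`. Boundary
#' conventions: `|r| >= 1 - 1e-12` is dependent (no transform attempted);
#' when `n - |Y| - 3 < 1` the test cannot reject dependence, so the pair is
#' reported dependent with a warning.
#'
#' @inheritParams partial_correlation
#' @param config A [ci_config()].
#' @return `TRUE` if conditionally independent at threshold `config$t`.
#' @export
is_independent <- function(data, i, j, Y = character(), config = ci_config()) {
  if (data$n - length(Y) - 3 < 1) {
    warning(
      "order-", length(Y), " test skipped (n too small); ",
      "pair treated as dependent"
    )
    return(FALSE)
  }
  r <- partial_correlation(data, i, j, Y)
  if (abs(r) >= 1 - 1e-12) {
    return(FALSE)
  }
  ci_statistic(r, data$n, length(Y)) <= config$t
}

#' Build a Gaussian CI-test callable
#'
#' Wraps a dataset into a function `f(i, j, Y)` answering conditional
#' independence queries with the partial-correlation test, precomputing the
#' (optionally shrunken) correlation matrix once. The callable can be passed
#' to [pc_skeleton()] in place of the exact d-separation oracle.
#'
#' @param data An [expression_dataset()].
#' @param config A [ci_config()].
#' @return A function of class `gaussian_ci` with signature `(i, j, Y)`.
#' @export
gaussian_ci_test <- function(data, config = ci_config()) {
  stats <- correlation_stats(data, shrinkage = config$shrinkage)
  R <- stats$R
  n <- stats$n
  t <- config$t
  idx <- stats::setNames(seq_along(stats$variables), stats$variables)
  f <- function(i, j, Y = character()) {
    ii <- idx[[i]]
    jj <- idx[[j]]
    yy <- unname(idx[as.character(Y)])
    if (n - length(yy) - 3 < 1) {
      warning(
        "order-", length(yy), " test skipped (n too small); ",
        "pair treated as dependent"
      )
      return(FALSE)
    }
    r <- pcor_from_cor_cpp(R, ii, jj, as.integer(yy))
    if (is.na(r) || abs(r) >= 1 - 1e-12) {
      return(FALSE)
    }
    abs(fisher_z(r)) * sqrt(n - length(yy) - 3) <= t
  }
  structure(f,
    class = c("gaussian_ci", "function"),
    corr = R, n = n, t = t, variables = stats$variables
  )
}
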