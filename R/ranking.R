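# Regulatory-importance ranking.
#
# A feature's rank R(f_i) satisfies
#   R(f_i) = (1 - d)/N + d * sum_{f_j in T(f_i)} R(f_j) / L(f_j)
# where T(f_i) is the set of targets of f_i and L(f_j) the number of
# regulators of f_j: rank flows from targets back to their regulators, so a
# molecule regulating many (well-regulated) targets scores high.  This is
# the reverse-orientation analogue of PageRank with one deliberate
# difference from the canonical algorithm: mass reaching target-free
# features is NOT redistributed, so the ranks sum to at most 1 and equal 1
# only when every feature has at least one regulator.

# sparse propagation matrix M with M[i, j] = 1/L(j) if i -> j is an edge.
# R_new = (1-d)/N + d * M %*% R
propagation_matrix <- function(net, sparse = TRUE) {
  feats <- net$nodes$feature
  n <- length(feats)
  idx <- stats::setNames(seq_len(n), feats)
  i <- idx[net$edges$regulator]
  j <- idx[net$edges$target]
  L <- node_degrees(net)$in_degree
  x <- 1 / L[j]
  if (sparse) {
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  } else {
    m <- matrix(0, n, n)
    if (length(i)) m[cbind(i, j)] <- x
    m
  }
}

rank_result <- function(net, r, iterations, converged, d) {
  deg <- node_degrees(net)
  out <- data.frame(
    feature = net$nodes$feature,
    class = net$nodes$class,
    rank = as.numeric(r),
    in_degree = unname(deg$in_degree),
    out_degree = unname(deg$out_degree),
    stringsAsFactors = FALSE
  )
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  attr(out, "damping") <- d
  class(out) <- c("rank_vector", "data.frame")
  out
}

#' Rank features by regulatory importance
#'
#' Computes the fixed point of the reverse-orientation PageRank recursion by
#' synchronous (Jacobi) power iteration from the uniform vector `1/N`,
#' stopping when the L1 change falls below `tol` or after `max_iter`
#' iterations.  Isolated features receive the baseline teleport rank
#' `(1 - d)/N`.
#'
#' @param net A `regulatory_network` from [build_network()].
#' @param d Damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance (> 0).
#' @param max_iter Maximum number of iterations (>= 1).
#' @return A `rank_vector` data frame with columns `feature`, `class`,
#'   `rank`, `in_degree`, `out_degree` and attributes `iterations`,
#'   `converged`, `damping`.
#' @seealso [rank_features_direct()] for the dense linear-system solve used
#'   as a cross-check.
#' @export
rank_features <- function(net, d = 0.85, tol = 1e-9, max_iter = 1000L) {
  stopifnot(inherits(net, "regulatory_network"))
  assert_scalar_number(d, "d", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(tol, "tol", 0, strict_lower = TRUE)
  assert_scalar_number(max_iter, "max_iter", 1)
  n <- network_size(net)
  if (n < 1L) stop_wsnf("empty network", class = "wsnf_empty_error")
  M <- propagation_matrix(net, sparse = TRUE)
  teleport <- (1 - d) / n
  r <- rep(1 / n, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r_new <- teleport + d * as.numeric(M %*% r)
    if (any(!is.finite(r_new))) {
      stop_wsnf("non-finite rank encountered", class = "wsnf_numeric_error")
    }
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  rank_result(net, r, iter, converged, d)
}

#' Solve the ranking fixed point directly
#'
#' Solves `(I - d M) R = ((1 - d)/N) 1` with a dense LU factorisation, where
#' `M[i, j] = 1/L(f_j)` for each edge `f_i -> f_j`.  Intended as an exact
#' reference for [rank_features()] on small graphs.
#'
#' @inheritParams rank_features
#' @return A `rank_vector` data frame (see [rank_features()]).
#' @export
rank_features_direct <- function(net, d = 0.85) {
  stopifnot(inherits(net, "regulatory_network"))
  assert_scalar_number(d, "d", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  n <- network_size(net)
  if (n < 1L) stop_wsnf("empty network", class = "wsnf_empty_error")
  if (n > 5000L) {
    stop_wsnf("direct solve is guarded to N <= 5000 features",
              class = "wsnf_domain_error")
  }
  M <- propagation_matrix(net, sparse = FALSE)
  r <- solve(diag(n) - d * M, rep((1 - d) / n, n))
  if (any(!is.finite(r))) {
    stop_wsnf("singular or ill-conditioned system", class = "wsnf_numeric_error")
  }
  rank_result(net, r, NA_integer_, TRUE, d)
}
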