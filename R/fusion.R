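# Weighted patient distances, affinity kernels, cross-network diffusion
# (similarity network fusion) and spectral clustering.

#' Weighted Euclidean distance between samples
#'
#' `Distance(S_i, S_j) = sqrt( sum_m W(f_m) * (f_m^{S_i} - f_m^{S_j})^2 )`
#' over the view's features — a Euclidean metric after rescaling every
#' feature by `sqrt(W)`.  With uniform weights `W = 1/p` this reduces to the
#' ordinary Euclidean distance divided by `sqrt(p)`.
#'
#' @param view Expression matrix (features x samples), no missing values.
#' @param weights A `weight_vector` from [feature_weights()] or a numeric
#'   vector named by feature; must cover every feature of the view, all
#'   entries >= 0.
#' @param standardize Z-score each feature across samples before computing
#'   distances (default TRUE; constant features are centred only).
#' @return Symmetric sample x sample distance matrix with zero diagonal and
#'   attribute `view` carrying the view's feature count.
#' @export
weighted_distance_matrix <- function(view, weights, standardize = TRUE) {
  assert_expression_matrix(view, "view")
  if (ncol(view) < 2L) {
    stop_wsnf("need >= 2 samples for a distance matrix",
              class = "wsnf_domain_error")
  }
  if (inherits(weights, "weight_vector")) {
    weights <- stats::setNames(weights$W, weights$feature)
  }
  if (is.null(names(weights))) {
    if (length(weights) != nrow(view)) {
      stop_wsnf("unnamed weights must match the view's feature count",
                class = "wsnf_domain_error")
    }
    names(weights) <- rownames(view)
  }
  missing_w <- setdiff(rownames(view), names(weights))
  if (length(missing_w)) {
    stop_wsnf("features without a weight: ",
              paste(utils::head(missing_w, 5L), collapse = ", "),
              class = "wsnf_domain_error")
  }
  w <- weights[rownames(view)]
  if (any(w < 0) || any(!is.finite(w))) {
    stop_wsnf("weights must be finite and nonnegative",
              class = "wsnf_domain_error")
  }
  x <- view
  if (standardize) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, stats::sd)
    x <- sweep(x, 1L, mu)
    pos <- sdv > 0
    x[pos, ] <- x[pos, , drop = FALSE] / sdv[pos]
  }
  d <- as.matrix(stats::dist(t(sqrt(w) * x)))
  diag(d) <- 0
  attr(d, "view") <- nrow(view)
  d
}

#' Affinity kernels from a distance matrix
#'
#' Scaled exponential kernel
#' `K(i, j) = exp(-D(i, j)^2 / (mu * eps_ij))` with the locally adaptive
#' bandwidth `eps_ij = (mean dist from i to its K nearest neighbours + the
#' same for j + D(i, j)) / 3`.  Two row-stochastic operators are derived:
#' the full-graph transition matrix `P` (diagonal 1/2, off-diagonal rows
#' summing 1/2) that carries similarity information, and the sparse local
#' operator `S` (row-normalised kernel restricted to each row's K nearest
#' neighbours, self excluded) that drives the diffusion.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param K Neighbourhood size (< number of samples); default 20.
#' @param mu Kernel bandwidth multiplier (> 0, typically 0.3-0.8);
#'   default 0.5.
#' @return Object of class `wsnf_affinity`: list with `kernel`, `P`, `S`.
#' @export
affinity_matrix <- function(D, K = 20L, mu = 0.5) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop_wsnf("`D` must be a square distance matrix", class = "wsnf_domain_error")
  }
  n <- nrow(D)
  if (K >= n) {
    stop_wsnf("neighbourhood size K must be < number of samples",
              class = "wsnf_domain_error")
  }
  assert_scalar_number(mu, "mu", 0, strict_lower = TRUE)
  if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0)) {
    stop_wsnf("`D` must be symmetric with zero diagonal",
              class = "wsnf_domain_error")
  }
  # mean distance from each sample to its K nearest other samples
  knn_mean <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i], partial = K)[seq_len(K)])
  }, numeric(1L))
  eps <- (outer(knn_mean, knn_mean, "+") + D) / 3
  floor_eps <- .Machine$double.eps
  if (any(eps <= 0)) {
    warning("zero kernel bandwidth for duplicate samples; epsilon floor applied",
            call. = FALSE)
    eps[eps <= 0] <- floor_eps
  }
  kern <- exp(-D^2 / (mu * eps))
  dimnames(kern) <- dimnames(D)

  P <- full_transition(kern)

  S <- matrix(0, n, n, dimnames = dimnames(D))
  for (i in seq_len(n)) {
    nn <- order(D[i, -i])[seq_len(K)]
    nn <- setdiff(seq_len(n), i)[nn]
    S[i, nn] <- kern[i, nn] / sum(kern[i, nn])
  }
  structure(list(kernel = kern, P = P, S = S), class = "wsnf_affinity")
}

# row-stochastic full kernel: diagonal 1/2, off-diagonal rows sum to 1/2
full_transition <- function(kern) {
  n <- nrow(kern)
  off <- kern
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- .Machine$double.eps
  P <- off / (2 * rs)
  diag(P) <- 1 / 2
  P
}

#' Fuse per-view similarity networks by cross-network diffusion
#'
#' For `m >= 2` views, each view's transition matrix is repeatedly diffused
#' through its local neighbourhood operator against the average of the other
#' views' matrices: `P(v) <- S(v) %*% (mean of other P) %*% t(S(v))`,
#' followed by re-normalisation (diagonal 1/2, off-diagonal rows summing
#' 1/2) and symmetrisation.  After `t` rounds the fused network is the
#' symmetrised mean of the per-view matrices.  A single view is returned as
#' its symmetrised full-graph transition matrix, with no diffusion.
#'
#' @param views List of `wsnf_affinity` objects sharing one sample set and
#'   order.
#' @param t Number of diffusion iterations (>= 1); default 20.
#' @param keep_history Keep the per-view matrices after every iteration
#'   (attribute `history`) for diagnostics.
#' @return Object of class `fused_network`: symmetric nonnegative matrix
#'   with attributes `iterations` and `view_status` (final per-view
#'   matrices).
#' @export
snf_fuse <- function(views, t = 20L, keep_history = FALSE) {
  if (inherits(views, "wsnf_affinity")) views <- list(views)
  if (!is.list(views) || length(views) == 0L) {
    stop_wsnf("need at least one view", class = "wsnf_domain_error")
  }
  stopifnot(all(vapply(views, inherits, logical(1L), "wsnf_affinity")))
  assert_scalar_number(t, "t", 1)
  ids <- lapply(views, function(v) rownames(v$P))
  if (length(views) > 1L) {
    same <- vapply(ids[-1L], identical, logical(1L), ids[[1L]])
    if (!all(same)) {
      stop_wsnf("views disagree on sample set/order",
                class = "wsnf_domain_error")
    }
  }
  m <- length(views)
  if (m == 1L) {
    P <- views[[1L]]$P
    fused <- (P + base::t(P)) / 2
    return(structure(fused, class = c("fused_network", class(fused)),
                     iterations = 0L, view_status = list(P)))
  }
  Ps <- lapply(views, `[[`, "P")
  Ss <- lapply(views, `[[`, "S")
  history <- if (keep_history) vector("list", t) else NULL
  for (iter in seq_len(t)) {
    new_Ps <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, Ps[-v]) / (m - 1)
      Pv <- Ss[[v]] %*% others %*% base::t(Ss[[v]])
      Pv <- full_transition(Pv)
      new_Ps[[v]] <- (Pv + base::t(Pv)) / 2
    }
    Ps <- new_Ps
    if (keep_history) history[[iter]] <- Ps
  }
  fused <- Reduce(`+`, Ps) / m
  fused <- (fused + base::t(fused)) / 2
  structure(fused, class = c("fused_network", class(fused)),
            iterations = as.integer(t), view_status = Ps,
            history = history)
}

normalized_laplacian_eigen <- function(W) {
  n <- nrow(W)
  deg <- rowSums(W)
  deg[deg <= 0] <- .Machine$double.eps
  d_inv_sqrt <- 1 / sqrt(deg)
  A <- W * (d_inv_sqrt %o% d_inv_sqrt)  # D^-1/2 W D^-1/2
  L <- diag(n) - A
  L <- (L + base::t(L)) / 2
  eigen(L, symmetric = TRUE)
}

#' Estimate the number of clusters by the eigengap heuristic
#'
#' Ranks candidate cluster counts by the gap between consecutive eigenvalues
#' of the normalized graph Laplacian of the fused similarity: a similarity
#' with k well-separated blocks has k near-zero eigenvalues followed by a
#' jump.  On a structureless (uniform) similarity no gap dominates; the
#' ranking is still returned.
#'
#' @param fused Fused similarity matrix (see [snf_fuse()]).
#' @param k_min,k_max Candidate range, `2 <= k_min <= k_max < n`.
#' @return `data.frame` with columns `k`, `eigengap`, sorted so the best
#'   candidate comes first; attribute `n_components` counts near-zero
#'   eigenvalues (connected components).
#' @export
estimate_num_clusters <- function(fused, k_min = 2L, k_max = 10L) {
  n <- nrow(fused)
  if (!(2 <= k_min && k_min <= k_max && k_max < n)) {
    stop_wsnf("need 2 <= k_min <= k_max < n", class = "wsnf_domain_error")
  }
  ev <- sort(normalized_laplacian_eigen(unclass(fused))$values)
  ks <- seq.int(k_min, k_max)
  gaps <- ev[ks + 1L] - ev[ks]
  out <- data.frame(k = ks, eigengap = gaps)
  out <- out[order(-out$eigengap, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_components") <- sum(ev < 1e-10)
  out
}

#' Spectral clustering of a fused similarity network
#'
#' Normalized spectral clustering: the eigenvectors of the normalized
#' Laplacian belonging to the k smallest eigenvalues are row-normalised to
#' unit length and partitioned by k-means (50 restarts, seeded).  Labels are
#' re-coded in order of first appearance, so identical input and seed give
#' identical output.
#'
#' @param fused Fused similarity matrix with sample dimnames.
#' @param k Number of clusters, `2 <= k < n`.
#' @param seed Integer RNG seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 50).
#' @return Object of class `subtype_assignment`: `data.frame` with columns
#'   `sample`, `cluster` (labels 1..k) and attributes `k`, `seed`.
#' @export
spectral_cluster <- function(fused, k, seed = 1L, nstart = 50L) {
  n <- nrow(fused)
  if (!(2 <= k && k < n)) {
    stop_wsnf("need 2 <= k < n samples", class = "wsnf_domain_error")
  }
  eig <- normalized_laplacian_eigen(unclass(fused))
  # columns of U: eigenvectors for the k smallest eigenvalues
  U <- eig$vectors[, rev(seq.int(n - k + 1L, n)), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  km <- with_seed(seed, stats::kmeans(U, centers = k, nstart = nstart,
                                      iter.max = 100L))
  labels <- match(km$cluster, unique(km$cluster))
  samples <- rownames(fused) %||% paste0("S", seq_len(n))
  out <- data.frame(sample = samples, cluster = labels,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("subtype_assignment", "data.frame")
  out
}
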