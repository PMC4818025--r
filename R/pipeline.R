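#' Run the full weighted similarity network fusion pipeline
#'
#' End-to-end subtype identification: regulatory ranks over the
#' miRNA-TF-mRNA network, per-feature weights combining rank and expression
#' variation, weighted patient distances per view (genes = mRNA + TF
#' features; miRNAs separate), affinity kernels, cross-network diffusion,
#' and spectral clustering of the fused similarity.
#'
#' @param gene_expr Preprocessed gene (mRNA + TF) expression matrix
#'   (features x samples).
#' @param mirna_expr Preprocessed miRNA expression matrix over the same
#'   samples.
#' @param net A `regulatory_network` whose nodes are contained in the union
#'   of the two views' features.
#' @param beta Weighting parameter in \[0, 1\] (default 0.8); `beta = 0`
#'   reproduces unweighted similarity network fusion up to a constant factor
#'   when expression variation is uniform.
#' @param d Damping factor of the rank recursion (default 0.85).
#' @param K Affinity neighbourhood size (default 20, capped at n - 1).
#' @param mu Kernel bandwidth multiplier (default 0.5).
#' @param t Diffusion iterations (default 20).
#' @param k Number of subtypes, or `"auto"` for the eigengap estimate.
#' @param seed RNG seed for the clustering step.
#' @param standardize Z-score features per view before distances.
#' @param normalization Weight normalisation mode, `"joint"` or
#'   `"per-view"` (see [feature_weights()]).
#' @return Object of class `wsnf_result`: list with `assignment`
#'   (`subtype_assignment`), `fused` (`fused_network`), `weights`
#'   (`weight_vector`), `ranks`, `k_candidates` (when `k = "auto"`), and
#'   `params`.
#' @export
run_wsnf <- function(gene_expr, mirna_expr, net, beta = 0.8, d = 0.85,
                     K = 20L, mu = 0.5, t = 20L, k = "auto", seed = 1L,
                     standardize = TRUE,
                     normalization = c("joint", "per-view")) {
  normalization <- match.arg(normalization)
  assert_expression_matrix(gene_expr, "gene_expr")
  assert_expression_matrix(mirna_expr, "mirna_expr")
  stopifnot(inherits(net, "regulatory_network"))

  if (!setequal(colnames(gene_expr), colnames(mirna_expr))) {
    off <- c(setdiff(colnames(gene_expr), colnames(mirna_expr)),
             setdiff(colnames(mirna_expr), colnames(gene_expr)))
    stop_wsnf("views disagree on samples: ",
              paste(utils::head(off, 5L), collapse = ", "),
              class = "wsnf_domain_error")
  }
  mirna_expr <- mirna_expr[, colnames(gene_expr), drop = FALSE]
  feats <- c(rownames(gene_expr), rownames(mirna_expr))
  extra <- setdiff(net$nodes$feature, feats)
  if (length(extra)) {
    stop_wsnf("network features absent from the expression views: ",
              paste(utils::head(extra, 5L), collapse = ", "),
              class = "wsnf_domain_error")
  }

  n <- ncol(gene_expr)
  K <- min(K, n - 1L)

  ranks <- rank_features(net, d = d)
  weights <- feature_weights(ranks, gene_expr, mirna_expr, beta = beta,
                             normalization = normalization)
  w <- stats::setNames(weights$W, weights$feature)

  affinities <- lapply(list(gene_expr, mirna_expr), function(view) {
    Dv <- weighted_distance_matrix(view, w[rownames(view)],
                                   standardize = standardize)
    affinity_matrix(Dv, K = K, mu = mu)
  })
  fused <- snf_fuse(affinities, t = t)

  k_candidates <- NULL
  if (identical(k, "auto")) {
    k_candidates <- estimate_num_clusters(fused, 2L, min(10L, n - 1L))
    k <- k_candidates$k[1L]
  }
  assignment <- spectral_cluster(fused, k = k, seed = seed)

  structure(
    list(assignment = assignment, fused = fused, weights = weights,
         ranks = ranks, k_candidates = k_candidates,
         params = list(beta = beta, d = d, K = K, mu = mu, t = t,
                       k = as.integer(k), seed = as.integer(seed),
                       standardize = standardize,
                       normalization = normalization)),
    class = "wsnf_result"
  )
}

#' @export
print.wsnf_result <- function(x, ...) {
  p <- x$params
  cat("weighted similarity network fusion result\n")
  cat(sprintf("  %d samples, k = %d subtypes (beta = %g, K = %d, mu = %g, t = %d, seed = %d)\n",
              nrow(x$assignment), p$k, p$beta, p$K, p$mu, p$t, p$seed))
  print(table(subtype = x$assignment$cluster))
  invisible(x)
}
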