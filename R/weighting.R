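# Feature weights: W(f) = beta * RN(f) + (1 - beta) * MADN(f), where RN is
# the simplex-normalised regulatory rank and MADN the simplex-normalised
# median absolute deviation of expression across samples.

#' Median absolute deviation of an expression vector
#'
#' `median(|x - median(x)|)` with midpoint medians for even lengths and no
#' consistency scaling constant (this is a raw variation measure, not a
#' robust sigma estimate).
#'
#' @param x Numeric vector of expression values across samples.
#' @return Nonnegative scalar.
#' @export
expression_mad <- function(x) {
  if (length(x) < 1L) {
    stop_wsnf("empty expression vector", class = "wsnf_empty_error")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_wsnf("expression vector contains missing or non-finite values; ",
              "impute before computing variation", class = "wsnf_domain_error")
  }
  stats::median(abs(x - stats::median(x)))
}

#' Normalise a nonnegative vector onto the probability simplex
#'
#' @param v Nonnegative numeric vector with at least one positive entry.
#' @return `v / sum(v)`; sums to 1.
#' @export
normalize_simplex <- function(v) {
  if (any(!is.finite(v))) {
    stop_wsnf("non-finite entries", class = "wsnf_numeric_error")
  }
  if (any(v < 0)) {
    stop_wsnf("negative entries cannot be simplex-normalised",
              class = "wsnf_domain_error")
  }
  s <- sum(v)
  if (s == 0) {
    stop_wsnf("all-zero vector cannot be simplex-normalised",
              class = "wsnf_degenerate_error")
  }
  v / s
}

#' Combine normalised rank and variation into feature weights
#'
#' `W = beta * RN + (1 - beta) * MADN`.  Both inputs must lie on the
#' probability simplex, so the convex combination does too.
#'
#' @param rn Simplex-normalised rank vector.
#' @param madn Simplex-normalised variation vector (same length).
#' @param beta Network-importance tuning parameter in \[0, 1\]; the default
#'   0.8 emphasises the regulatory-network information.
#' @return Numeric weight vector summing to 1.
#' @export
combine_weights <- function(rn, madn, beta = 0.8) {
  assert_scalar_number(beta, "beta", 0, 1)
  if (length(rn) != length(madn)) {
    stop_wsnf("rank and variation vectors differ in length",
              class = "wsnf_domain_error")
  }
  if (abs(sum(rn) - 1) > 1e-6 || abs(sum(madn) - 1) > 1e-6) {
    stop_wsnf("inputs must be simplex-normalised (sum to 1)",
              class = "wsnf_domain_error")
  }
  beta * rn + (1 - beta) * madn
}

#' Per-feature weights from a ranking and two expression views
#'
#' Computes the median absolute deviation of every feature across samples of
#' its view, normalises ranks and variations, and combines them.  With
#' `normalization = "joint"` (the default, the literal reading of the
#' normalisation step) RN and MADN are each normalised over all N network
#' features regardless of view; `"per-view"` normalises gene-view and
#' miRNA-view features separately, guarding against the two views' different
#' expression scales.
#'
#' @param ranks A `rank_vector` from [rank_features()].
#' @param gene_expr,mirna_expr Preprocessed expression matrices
#'   (features x samples); every ranked feature must appear in exactly one.
#' @param beta Tuning parameter in \[0, 1\] (see [combine_weights()]).
#' @param normalization `"joint"` or `"per-view"`.
#' @return A `weight_vector` data frame with columns `feature`, `class`,
#'   `rank`, `RN`, `MAD`, `MADN`, `W` and attributes `beta`, `normalization`.
#' @export
feature_weights <- function(ranks, gene_expr, mirna_expr, beta = 0.8,
                            normalization = c("joint", "per-view")) {
  stopifnot(inherits(ranks, "rank_vector"))
  normalization <- match.arg(normalization)
  assert_scalar_number(beta, "beta", 0, 1)
  assert_expression_matrix(gene_expr, "gene_expr")
  assert_expression_matrix(mirna_expr, "mirna_expr")

  feats <- ranks$feature
  in_gene <- feats %in% rownames(gene_expr)
  in_mirna <- feats %in% rownames(mirna_expr)
  if (any(in_gene & in_mirna)) {
    stop_wsnf("features present in both views: ",
              paste(utils::head(feats[in_gene & in_mirna], 5L), collapse = ", "),
              class = "wsnf_conflict_error")
  }
  if (any(!in_gene & !in_mirna)) {
    stop_wsnf("ranked features missing from both expression views: ",
              paste(utils::head(feats[!in_gene & !in_mirna], 5L), collapse = ", "),
              class = "wsnf_domain_error")
  }
  mad_all <- numeric(length(feats))
  mad_all[in_gene] <- apply(gene_expr[feats[in_gene], , drop = FALSE], 1L,
                            expression_mad)
  mad_all[in_mirna] <- apply(mirna_expr[feats[in_mirna], , drop = FALSE], 1L,
                             expression_mad)

  if (normalization == "joint") {
    rn <- normalize_simplex(ranks$rank)
    madn <- normalize_simplex(mad_all)
    w <- combine_weights(rn, madn, beta)
  } else {
    rn <- madn <- w <- numeric(length(feats))
    for (sel in list(in_gene, in_mirna)) {
      rn[sel] <- normalize_simplex(ranks$rank[sel])
      madn[sel] <- normalize_simplex(mad_all[sel])
      w[sel] <- combine_weights(rn[sel], madn[sel], beta)
    }
    # per-view vectors each sum to 1; rescale so the full vector does too
    w <- w / 2
  }
  out <- data.frame(feature = feats, class = ranks$class, rank = ranks$rank,
                    RN = rn, MAD = mad_all, MADN = madn, W = w,
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- beta
  attr(out, "normalization") <- normalization
  class(out) <- c("weight_vector", "data.frame")
  out
}

#' GeneRank-style weights (diagnostic)
#'
#' The GeneRank/NCIS approach folds expression variation into the rank
#' recursion itself, replacing the uniform teleport term with the normalised
#' variation:
#' `W(f_i) = (1 - d) * MADN(f_i) + d * sum_{f_j in T(f_i)} W(f_j)/L(f_j)`.
#' Provided to reproduce the diagnostic that such weights are dominated by
#' network topology: they correlate strongly with the rank-only solution, so
#' the variation information is largely lost (the motivation for the linear
#' model in [combine_weights()]).
#'
#' @param net A `regulatory_network`.
#' @param mad_values Per-feature variation, a numeric vector named by
#'   feature or ordered as `net$nodes`.
#' @param d Damping factor in (0, 1).
#' @param tol,max_iter Power-iteration controls.
#' @return Numeric weight vector in node order.
#' @export
generank_weights <- function(net, mad_values, d = 0.85, tol = 1e-9,
                             max_iter = 1000L) {
  stopifnot(inherits(net, "regulatory_network"))
  assert_scalar_number(d, "d", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  feats <- net$nodes$feature
  if (!is.null(names(mad_values))) {
    if (!all(feats %in% names(mad_values))) {
      stop_wsnf("mad_values missing features", class = "wsnf_domain_error")
    }
    mad_values <- mad_values[feats]
  }
  if (length(mad_values) != length(feats)) {
    stop_wsnf("mad_values length does not match network size",
              class = "wsnf_domain_error")
  }
  madn <- normalize_simplex(mad_values)
  M <- propagation_matrix(net, sparse = TRUE)
  w <- madn
  for (i in seq_len(max_iter)) {
    w_new <- (1 - d) * madn + d * as.numeric(M %*% w)
    if (sum(abs(w_new - w)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  unname(w)
}

#' Correlation of candidate weights with the rank-only solution
#'
#' Pearson correlations of two candidate weight vectors against the raw
#' regulatory ranks — the diagnostic showing that recursion-embedded
#' (GeneRank-style) weights track the rank-only solution far more closely
#' than the linear-model weights do.
#'
#' @param ranks A `rank_vector` or a numeric rank vector.
#' @param w_generank_style,w_linear Candidate weight vectors (same length as
#'   the ranks, >= 3 entries).
#' @return Named numeric vector `c(generank = ..., linear = ...)` of Pearson
#'   correlations.
#' @export
rank_weight_correlation <- function(ranks, w_generank_style, w_linear) {
  r <- if (inherits(ranks, "rank_vector")) ranks$rank else as.numeric(ranks)
  if (length(r) < 3L || length(w_generank_style) != length(r) ||
      length(w_linear) != length(r)) {
    stop_wsnf("need >= 3 features and equal-length weight vectors",
              class = "wsnf_domain_error")
  }
  if (stats::sd(r) == 0 || stats::sd(w_generank_style) == 0 ||
      stats::sd(w_linear) == 0) {
    stop_wsnf("zero-variance input: correlation undefined",
              class = "wsnf_degenerate_error")
  }
  c(generank = stats::cor(r, w_generank_style),
    linear = stats::cor(r, w_linear))
}
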