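# Expression-matrix preparation: log2 transform, k-nearest-neighbour
# imputation, low-mean quantile filter, low-SD filter.  All filters remove
# features only; samples are never touched.

#' Log2-transform an expression matrix
#'
#' @param m Nonnegative expression matrix (features x samples).
#' @param pseudocount Nonnegative constant added before the log; default 1,
#'   appropriate for count-like RNA-seq values.
#' @return Matrix of `log2(m + pseudocount)`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  assert_expression_matrix(m, "m", allow_na = TRUE)
  assert_scalar_number(pseudocount, "pseudocount", 0)
  if (any(m < 0, na.rm = TRUE)) {
    stop_wsnf("negative expression values cannot be log2-transformed",
              class = "wsnf_domain_error")
  }
  log2(m + pseudocount)
}

#' Impute missing expression values by feature k-nearest neighbours
#'
#' For each missing cell, the `k` features closest to the incomplete feature
#' (Euclidean distance on co-observed samples, scaled to a per-sample
#' root-mean-square so different overlaps are comparable) that are observed
#' at that sample donate their values, combined by an inverse-distance
#' weighted mean.  An exactly matching feature (distance 0) therefore
#' dominates.
#'
#' @param m Expression matrix with `NA` for missing cells; every feature
#'   must have at least one observed value.
#' @param k Number of neighbouring features; default 10.
#' @return Matrix with no missing values.
#' @export
impute_missing <- function(m, k = 10L) {
  assert_expression_matrix(m, "m", allow_na = TRUE)
  assert_scalar_number(k, "k", 1)
  if (!anyNA(m)) return(m)
  fully_missing <- rownames(m)[rowSums(!is.na(m)) == 0L]
  if (length(fully_missing)) {
    stop_wsnf("feature(s) with no observed values: ",
              paste(utils::head(fully_missing, 10L), collapse = ", "),
              class = "wsnf_domain_error")
  }
  out <- m
  incomplete <- which(rowSums(is.na(m)) > 0L)
  for (i in incomplete) {
    others <- setdiff(seq_len(nrow(m)), i)
    # rms distance over co-observed samples
    diffs <- sweep(m[others, , drop = FALSE], 2L, m[i, ])
    sq <- diffs^2
    n_co <- rowSums(!is.na(sq))
    dist_i <- sqrt(rowMeans(sq, na.rm = TRUE))
    dist_i[n_co == 0L] <- Inf
    for (s in which(is.na(m[i, ]))) {
      donors <- others[!is.na(m[others, s]) & is.finite(dist_i)]
      if (!length(donors)) {
        stop_wsnf("no donor features observed at sample ", colnames(m)[s],
                  class = "wsnf_domain_error")
      }
      dd <- dist_i[match(donors, others)]
      ord <- order(dd)[seq_len(min(k, length(donors)))]
      nn <- donors[ord]
      nd <- dd[ord]
      if (any(nd == 0)) {
        out[i, s] <- mean(m[nn[nd == 0], s])
      } else {
        w <- 1 / nd
        out[i, s] <- sum(w * m[nn, s]) / sum(w)
      }
    }
  }
  out
}

#' Remove the lowest-mean fraction of features
#'
#' Features are ranked by their mean across samples and the lowest
#' `floor(drop_fraction * n_features)` are removed; among tied means the
#' earlier row is kept.
#'
#' @param m Expression matrix with no missing values.
#' @param drop_fraction Fraction in \[0, 1) of features to drop (e.g. 0.25
#'   for genes, 0.60 for miRNAs in RNA-seq-style data).
#' @return Matrix with the surviving features, input order preserved.
#' @export
filter_low_mean <- function(m, drop_fraction) {
  assert_expression_matrix(m, "m")
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1) {
    stop_wsnf("`drop_fraction` must be in [0, 1)", class = "wsnf_domain_error")
  }
  n_drop <- floor(drop_fraction * nrow(m))
  if (n_drop == 0L) return(m)
  means <- rowMeans(m)
  # ascending mean; among ties drop the later row first, keeping earlier rows
  drop_order <- order(means, -seq_len(nrow(m)))
  drop_idx <- drop_order[seq_len(n_drop)]
  m[-drop_idx, , drop = FALSE]
}

#' Remove features with low standard deviation
#'
#' Sample standard deviation (n - 1 denominator) strictly below `threshold`
#' removes the feature; equality keeps it.
#'
#' @param m Expression matrix with no missing values and >= 2 samples.
#' @param threshold Nonnegative SD cutoff (e.g. 0.5 for log2 RNA-seq genes,
#'   0.6 / 0.2 for microarray genes / miRNAs).
#' @return Matrix with the surviving features.
#' @export
filter_low_sd <- function(m, threshold) {
  assert_expression_matrix(m, "m")
  assert_scalar_number(threshold, "threshold", 0)
  if (ncol(m) < 2L) {
    stop_wsnf("standard deviation needs >= 2 samples",
              class = "wsnf_domain_error")
  }
  sds <- apply(m, 1L, stats::sd)
  m[sds >= threshold, , drop = FALSE]
}

#' Standard preprocessing pipelines
#'
#' Convenience wrapper applying the two stated preparation orders:
#' `"rnaseq"` runs log2 -> low-mean filter -> low-SD filter (the RNA-seq
#' path); `"microarray"` runs imputation -> low-SD filter.  The order used
#' is recorded in the `steps` attribute.
#'
#' @param m Raw expression matrix.
#' @param mode `"rnaseq"` or `"microarray"`.
#' @param pseudocount Pseudocount for the log2 transform (rnaseq mode).
#' @param drop_fraction Low-mean drop fraction (rnaseq mode).
#' @param sd_threshold SD cutoff applied last in both modes.
#' @param k Neighbour count for imputation (microarray mode).
#' @return Preprocessed matrix with attribute `steps`.
#' @export
preprocess_expression <- function(m, mode = c("rnaseq", "microarray"),
                                  pseudocount = 1, drop_fraction = 0.25,
                                  sd_threshold = 0.5, k = 10L) {
  mode <- match.arg(mode)
  if (mode == "rnaseq") {
    out <- log2_transform(m, pseudocount)
    out <- filter_low_mean(out, drop_fraction)
    out <- filter_low_sd(out, sd_threshold)
    attr(out, "steps") <- c("log2", "filter_low_mean", "filter_low_sd")
  } else {
    out <- impute_missing(m, k)
    out <- filter_low_sd(out, sd_threshold)
    attr(out, "steps") <- c("impute", "filter_low_sd")
  }
  out
}
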