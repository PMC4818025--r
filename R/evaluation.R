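# Subtype validation: silhouette widths on the fused similarity, core-sample
# extraction, multi-group log-rank survival tests, adjusted Rand index.

#' Dissimilarity from a fused similarity matrix
#'
#' Off-diagonal similarities are min-max scaled to \[0, 1\] and flipped
#' (`D = 1 - scaled`), diagonal set to 0.  If all off-diagonal similarities
#' are equal the matrix is degenerate and a constant dissimilarity of 0.5 is
#' returned (silhouette widths are then ~ 0 by construction).
#'
#' @param fused Symmetric similarity matrix.
#' @return Symmetric dissimilarity matrix in \[0, 1\] with zero diagonal.
#' @export
similarity_to_dissimilarity <- function(fused) {
  W <- unclass(fused)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  off <- W[row(W) != col(W)]
  rng <- range(off)
  if (diff(rng) == 0) {
    D <- matrix(0.5, nrow(W), ncol(W), dimnames = dimnames(W))
  } else {
    D <- 1 - (W - rng[1L]) / diff(rng)
  }
  diag(D) <- 0
  D
}

#' Silhouette widths of a subtype assignment on the fused network
#'
#' Standard silhouette `s_i = (b_i - a_i) / max(a_i, b_i)` on the
#' dissimilarity `1 - `min-max-scaled fused similarity, with `a_i` the mean
#' within-cluster dissimilarity (self excluded) and `b_i` the smallest mean
#' dissimilarity to another cluster.  Samples in singleton clusters get
#' width 0.
#'
#' @param fused Fused similarity matrix with sample dimnames.
#' @param labels A `subtype_assignment` (see [spectral_cluster()]) or an
#'   integer vector of cluster labels in sample order.
#' @return Object of class `wsnf_silhouette`: list with `widths` (data frame
#'   `sample`, `cluster`, `neighbor`, `width`), `cluster_sizes` and
#'   `average_width`.
#' @export
silhouette_from_similarity <- function(fused, labels) {
  D <- similarity_to_dissimilarity(fused)
  lab <- assignment_labels(labels, rownames(D))
  k <- length(unique(lab))
  if (k < 2L) {
    stop_wsnf("silhouette needs >= 2 clusters", class = "wsnf_domain_error")
  }
  sil <- cluster::silhouette(lab, dmatrix = D)
  widths <- data.frame(
    sample = rownames(D) %||% paste0("S", seq_along(lab)),
    cluster = as.integer(sil[, "cluster"]),
    neighbor = as.integer(sil[, "neighbor"]),
    width = as.numeric(sil[, "sil_width"]),
    stringsAsFactors = FALSE
  )
  structure(
    list(widths = widths,
         cluster_sizes = table(widths$cluster),
         average_width = mean(widths$width)),
    class = "wsnf_silhouette"
  )
}

#' @export
print.wsnf_silhouette <- function(x, ...) {
  cat("silhouette over", nrow(x$widths), "samples in",
      length(x$cluster_sizes), "clusters; average width",
      format(x$average_width, digits = 4L), "\n")
  invisible(x)
}

#' Core samples of a clustering
#'
#' Samples with negative silhouette width sit closer to another subtype
#' than to their own and are discarded; zero widths are kept.
#'
#' @param sil A `wsnf_silhouette` from [silhouette_from_similarity()].
#' @return Character vector of retained sample ids, with attribute
#'   `per_cluster` (retained counts by subtype).
#' @export
core_samples <- function(sil) {
  stopifnot(inherits(sil, "wsnf_silhouette"))
  keep <- sil$widths$width >= 0
  out <- sil$widths$sample[keep]
  attr(out, "per_cluster") <- table(sil$widths$cluster[keep])
  out
}

# labels as integer vector aligned to `samples`
assignment_labels <- function(labels, samples = NULL) {
  if (inherits(labels, "subtype_assignment") || is.data.frame(labels)) {
    if (!is.null(samples)) {
      idx <- match(samples, labels$sample)
      if (anyNA(idx)) {
        stop_wsnf("samples without a cluster label: ",
                  paste(utils::head(samples[is.na(idx)], 5L), collapse = ", "),
                  class = "wsnf_domain_error")
      }
      as.integer(labels$cluster[idx])
    } else {
      as.integer(labels$cluster)
    }
  } else {
    as.integer(labels)
  }
}

#' Multi-group log-rank test of survival separation
#'
#' Standard k-group log-rank test: at every distinct event time observed
#' events per group are compared with their hypergeometric expectation given
#' the risk sets, and the accumulated (O - E) vector is combined through its
#' variance matrix into a chi-square statistic on k - 1 degrees of freedom
#' (computed via [survival::survdiff()]).
#'
#' @param surv `data.frame` with columns `sample`, `time`, `event`
#'   (event 1 = observed, 0 = censored); see [read_survival()].
#' @param labels A `subtype_assignment` or vector of group labels named by
#'   sample (or aligned with `surv$sample`).
#' @return List with `statistic`, `df` (= k - 1) and `p_value`.
#' @export
logrank_test <- function(surv, labels) {
  stopifnot(is.data.frame(surv),
            all(c("sample", "time", "event") %in% names(surv)))
  if (any(surv$time < 0) || !all(surv$event %in% c(0, 1))) {
    stop_wsnf("need nonnegative times and 0/1 event indicators",
              class = "wsnf_domain_error")
  }
  if (inherits(labels, "subtype_assignment") || is.data.frame(labels)) {
    grp <- assignment_labels(labels, surv$sample)
  } else if (!is.null(names(labels))) {
    idx <- match(surv$sample, names(labels))
    if (anyNA(idx)) {
      stop_wsnf("survival samples without a group label",
                class = "wsnf_domain_error")
    }
    grp <- labels[idx]
  } else {
    if (length(labels) != nrow(surv)) {
      stop_wsnf("labels must align with the survival table",
                class = "wsnf_domain_error")
    }
    grp <- labels
  }
  k <- length(unique(grp))
  if (k < 2L) {
    stop_wsnf("log-rank needs >= 2 groups", class = "wsnf_domain_error")
  }
  if (sum(surv$event) == 0) {
    stop_wsnf("all records censored: no events to compare",
              class = "wsnf_domain_error")
  }
  fit <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  df <- k - 1L
  stat <- as.numeric(fit$chisq)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement via the contingency-table formula; 1 iff the
#' partitions are identical up to relabeling, ~0 for independent labelings.
#'
#' @param a,b `subtype_assignment`s or label vectors over the same samples
#'   (matched by sample id when both carry ids).
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  a_df <- inherits(a, "subtype_assignment") || is.data.frame(a)
  b_df <- inherits(b, "subtype_assignment") || is.data.frame(b)
  if (a_df && b_df) {
    if (!setequal(a$sample, b$sample)) {
      stop_wsnf("partitions cover different sample sets",
                class = "wsnf_domain_error")
    }
    x <- assignment_labels(a)
    y <- assignment_labels(b, a$sample)
  } else {
    x <- assignment_labels(a)
    y <- assignment_labels(b)
    if (length(x) != length(y)) {
      stop_wsnf("partitions cover different sample sets",
                class = "wsnf_domain_error")
    }
  }
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
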