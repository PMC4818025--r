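#' Read an expression matrix from TSV
#'
#' The file must have a header whose first column is `feature`; remaining
#' columns are sample ids.  Missing values are encoded `NA`.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    stop_wsnf("file not found: ", path, class = "wsnf_format_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || tolower(names(df)[1L]) != "feature") {
    stop_wsnf("expression TSV must start with a `feature` column: ", path,
              class = "wsnf_format_error")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- trimws(as.character(df[[1L]]))
  assert_expression_matrix(m, "expression matrix", allow_na = TRUE)
  m
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix (features x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  assert_expression_matrix(m, "m", allow_na = TRUE)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read feature class annotations
#'
#' Expects a TSV with header `feature<TAB>class`, class one of
#' `miRNA`, `TF`, `mRNA`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `feature`, `class`.
#' @export
read_feature_classes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("feature", "class") %in% names(df))) {
    stop_wsnf("feature class TSV needs `feature` and `class` columns: ", path,
              class = "wsnf_format_error")
  }
  df$feature <- trimws(df$feature)
  df$class <- trimws(df$class)
  bad <- setdiff(unique(df$class), FEATURE_CLASSES)
  if (length(bad)) {
    stop_wsnf("unknown feature classes: ", paste(bad, collapse = ", "),
              class = "wsnf_format_error")
  }
  df[, c("feature", "class")]
}

#' Assemble feature classes from expression views and a TF list
#'
#' Features of the miRNA view are classed `miRNA`; features of the gene view
#' are `TF` when they appear in `tf_list` and `mRNA` otherwise.  Identifier
#' matching is exact and case-sensitive.
#'
#' @param gene_features Character vector of gene-view feature ids (mRNA + TF).
#' @param mirna_features Character vector of miRNA-view feature ids.
#' @param tf_list Character vector of transcription factor symbols (one symbol
#'   per line when read from file).
#' @return `data.frame` with columns `feature`, `class`.
#' @export
infer_feature_classes <- function(gene_features, mirna_features, tf_list = character()) {
  gene_features <- trimws(gene_features)
  mirna_features <- trimws(mirna_features)
  overlap <- intersect(gene_features, mirna_features)
  if (length(overlap)) {
    stop_wsnf("features present in both views: ",
              paste(utils::head(overlap, 5L), collapse = ", "),
              class = "wsnf_conflict_error")
  }
  data.frame(
    feature = c(gene_features, mirna_features),
    class = c(ifelse(gene_features %in% trimws(tf_list), "TF", "mRNA"),
              rep("miRNA", length(mirna_features))),
    stringsAsFactors = FALSE
  )
}

#' Read a survival table
#'
#' Expects a CSV with header `sample,time,event` (time in days, event 1 =
#' death observed, 0 = censored).
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df))) {
    stop_wsnf("survival CSV needs `sample`, `time`, `event` columns: ", path,
              class = "wsnf_format_error")
  }
  if (any(!is.finite(df$time)) || any(df$time < 0)) {
    stop_wsnf("survival times must be finite and nonnegative",
              class = "wsnf_domain_error")
  }
  if (!all(df$event %in% c(0, 1))) {
    stop_wsnf("event must be 0 (censored) or 1 (observed)",
              class = "wsnf_domain_error")
  }
  df[, c("sample", "time", "event")]
}

#' Write a square similarity matrix with sample ids
#'
#' @param m Square numeric matrix with identical row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            identical(rownames(m), colnames(m)))
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square similarity matrix written by [write_similarity()]
#'
#' @param path Path to the TSV file.
#' @return Square numeric matrix with sample dimnames.
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  stopifnot(identical(rownames(m), colnames(m)))
  m
}
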