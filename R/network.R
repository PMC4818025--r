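#' Load a directed interaction edge list
#'
#' Reads a tab-separated edge list with header columns `regulator` and
#' `target` (a third `source` column is optional and kept as a free-text
#' provenance tag).  Identifiers are whitespace-trimmed; row order is
#' preserved.
#'
#' @param path Path to the edge-list TSV.
#' @param expected_class Either `"any"` or one of the six interaction classes
#'   (`"miRNA->mRNA"`, `"miRNA->TF"`, `"TF->miRNA"`, `"TF->mRNA"`, `"TF->TF"`,
#'   `"mRNA->mRNA"`).  When not `"any"`, [build_network()] checks that every
#'   resolved edge of this table has that class.
#' @return `data.frame` with columns `regulator`, `target`, `source` and
#'   attribute `expected_class`.
#' @export
load_interactions <- function(path, expected_class = "any") {
  valid <- c("any", unlist(lapply(names(ALLOWED_INTERACTIONS), function(r) {
    interaction_class_label(r, ALLOWED_INTERACTIONS[[r]])
  })))
  if (!expected_class %in% valid) {
    stop_wsnf("unknown interaction class: ", expected_class,
              class = "wsnf_domain_error")
  }
  if (!file.exists(path)) {
    stop_wsnf("file not found: ", path, class = "wsnf_format_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("regulator", "target") %in% names(df))) {
    stop_wsnf("edge list must have `regulator` and `target` columns: ", path,
              class = "wsnf_format_error")
  }
  if (nrow(df) == 0L) {
    stop_wsnf("edge list has a header but no rows: ", path,
              class = "wsnf_empty_error")
  }
  out <- data.frame(
    regulator = trimws(df$regulator),
    target = trimws(df$target),
    source = if ("source" %in% names(df)) trimws(df$source) else NA_character_,
    stringsAsFactors = FALSE
  )
  bad <- which(!nzchar(out$regulator) | !nzchar(out$target))
  if (length(bad)) {
    stop_wsnf("blank regulator/target at data line(s) ",
              paste(utils::head(bad, 10L), collapse = ", "), " of ", path,
              class = "wsnf_format_error")
  }
  attr(out, "expected_class") <- expected_class
  out
}

#' Build a typed regulatory network from interaction tables
#'
#' Merges one or more interaction tables into a single directed
#' miRNA-TF-mRNA regulatory graph restricted to the feature universe (the
#' union of features in the expression views, with their class labels).
#' Duplicate edges across tables collapse to one unweighted edge; self-loops
#' and edges with an endpoint outside the universe are dropped.  All dropped
#' and collapsed rows are counted in the result.  Every universe feature
#' becomes a node even when isolated, so that every feature later receives a
#' baseline rank.
#'
#' @param tables A single interaction table or a list of them
#'   (see [load_interactions()]).
#' @param universe `data.frame` with columns `feature` and `class`
#'   (class in `miRNA`/`TF`/`mRNA`); see [infer_feature_classes()].
#' @return Object of class `regulatory_network`: list with `nodes`
#'   (feature, class), `edges` (regulator, target, class) and `dropped`
#'   (named counts: duplicate, self_loop, outside_universe, incompatible).
#' @export
build_network <- function(tables, universe) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!is.data.frame(universe) ||
      !all(c("feature", "class") %in% names(universe))) {
    stop_wsnf("`universe` must have `feature` and `class` columns",
              class = "wsnf_format_error")
  }
  universe <- data.frame(feature = trimws(universe$feature),
                         class = trimws(universe$class),
                         stringsAsFactors = FALSE)
  if (nrow(universe) == 0L) {
    stop_wsnf("empty feature universe", class = "wsnf_empty_error")
  }
  if (!all(universe$class %in% FEATURE_CLASSES)) {
    stop_wsnf("universe classes must be miRNA/TF/mRNA",
              class = "wsnf_format_error")
  }
  # an id may carry exactly one class
  dup <- unique(universe$feature[duplicated(universe$feature)])
  conflicts <- dup[vapply(dup, function(f) {
    length(unique(universe$class[universe$feature == f])) > 1L
  }, logical(1L))]
  if (length(conflicts)) {
    stop_wsnf("features claimed as two classes: ",
              paste(utils::head(conflicts, 10L), collapse = ", "),
              class = "wsnf_conflict_error")
  }
  universe <- universe[!duplicated(universe$feature), , drop = FALSE]
  klass <- stats::setNames(universe$class, universe$feature)

  all_edges <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(regulator = tb$regulator, target = tb$target,
               expected = rep(attr(tb, "expected_class") %||% "any",
                              length(tb$regulator)),
               stringsAsFactors = FALSE)
  }))
  dropped <- c(duplicate = 0L, self_loop = 0L,
               outside_universe = 0L, incompatible = 0L)

  if (!is.null(all_edges) && nrow(all_edges)) {
    key <- paste(all_edges$regulator, all_edges$target, sep = "\r")
    dropped[["duplicate"]] <- sum(duplicated(key))
    all_edges <- all_edges[!duplicated(key), , drop = FALSE]

    self <- all_edges$regulator == all_edges$target
    dropped[["self_loop"]] <- sum(self)
    all_edges <- all_edges[!self, , drop = FALSE]

    inside <- all_edges$regulator %in% universe$feature &
      all_edges$target %in% universe$feature
    dropped[["outside_universe"]] <- sum(!inside)
    all_edges <- all_edges[inside, , drop = FALSE]

    cls <- interaction_class_label(klass[all_edges$regulator],
                                   klass[all_edges$target])
    ok <- mapply(function(r, t) t %in% ALLOWED_INTERACTIONS[[r]],
                 klass[all_edges$regulator], klass[all_edges$target])
    ok <- as.logical(ok)
    if (any(!ok)) {
      warning(sum(!ok), " edge(s) with a class-incompatible direction dropped",
              call. = FALSE)
    }
    dropped[["incompatible"]] <- sum(!ok)
    mismatch <- ok & all_edges$expected != "any" & cls != all_edges$expected
    if (any(mismatch)) {
      stop_wsnf("edges resolved to a class other than the table's declared ",
                "class, e.g. ", cls[mismatch][1L],
                class = "wsnf_conflict_error")
    }
    edges <- data.frame(regulator = all_edges$regulator[ok],
                        target = all_edges$target[ok],
                        class = cls[ok],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(regulator = character(), target = character(),
                        class = character(), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(
    list(nodes = universe, edges = edges, dropped = dropped),
    class = "regulatory_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.regulatory_network <- function(x, ...) {
  cat("miRNA-TF-mRNA regulatory network\n")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%s)", paste(names(table(x$nodes$class)),
                            table(x$nodes$class), sep = "=", collapse = ", ")),
      "\n")
  cat("  edges:", nrow(x$edges), "\n")
  if (any(x$dropped > 0)) {
    cat("  dropped:", paste(names(x$dropped), x$dropped,
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of features in a regulatory network
#' @param net A `regulatory_network`.
#' @return Integer node count.
#' @export
network_size <- function(net) nrow(net$nodes)

# in-degree L(f): number of regulators of each feature; out-degree |T(f)|
node_degrees <- function(net) {
  feats <- net$nodes$feature
  list(
    in_degree = stats::setNames(
      as.integer(table(factor(net$edges$target, levels = feats))), feats),
    out_degree = stats::setNames(
      as.integer(table(factor(net$edges$regulator, levels = feats))), feats)
  )
}

#' Summarise a regulatory network
#'
#' @param net A `regulatory_network` from [build_network()].
#' @return List with `nodes_by_class`, `edges_by_class` (both named integer
#'   vectors) and `dropped` counts from the merge.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  nodes_by_class <- stats::setNames(
    as.integer(table(factor(net$nodes$class, levels = FEATURE_CLASSES))),
    FEATURE_CLASSES)
  classes <- unlist(lapply(names(ALLOWED_INTERACTIONS), function(r) {
    interaction_class_label(r, ALLOWED_INTERACTIONS[[r]])
  }))
  edges_by_class <- stats::setNames(
    as.integer(table(factor(net$edges$class, levels = classes))), classes)
  list(nodes_by_class = nodes_by_class,
       edges_by_class = edges_by_class,
       n_edges = nrow(net$edges),
       dropped = net$dropped)
}
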