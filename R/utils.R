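# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_wsnf <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "wsnf_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_wsnf(sprintf("`%s` must be a single finite number", name),
              class = "wsnf_domain_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_wsnf(sprintf("`%s` = %g is outside its allowed range", name, x),
              class = "wsnf_domain_error")
  }
  invisible(x)
}

# features x samples numeric matrix with unique dimnames
assert_expression_matrix <- function(x, name = "x", allow_na = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_wsnf(sprintf("`%s` must be a numeric matrix (features x samples)", name),
              class = "wsnf_format_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_wsnf(sprintf("`%s` must have feature rownames and sample colnames", name),
              class = "wsnf_format_error")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop_wsnf(sprintf("`%s` has duplicated feature or sample ids", name),
              class = "wsnf_format_error")
  }
  if (!allow_na && anyNA(x)) {
    stop_wsnf(sprintf("`%s` contains missing values; impute first", name),
              class = "wsnf_domain_error")
  }
  invisible(x)
}

FEATURE_CLASSES <- c("miRNA", "TF", "mRNA")

# regulator class -> admissible target classes in the regulatory model
ALLOWED_INTERACTIONS <- list(
  miRNA = c("mRNA", "TF"),
  TF    = c("miRNA", "mRNA", "TF"),
  mRNA  = "mRNA"
)

interaction_class_label <- function(reg_class, tgt_class) {
  paste0(reg_class, "->", tgt_class)
}
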