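# Shared fixture builders. Everything is generated in code at test time.

# interaction table as load_interactions() would return it
interaction_table <- function(regulator, target, source = "test",
                              expected_class = "any") {
  out <- data.frame(regulator = regulator, target = target,
                    source = source, stringsAsFactors = FALSE)
  attr(out, "expected_class") <- expected_class
  out
}

# universe data.frame; default all-TF so every edge direction is admissible
make_universe <- function(ids, class = "TF") {
  data.frame(feature = ids, class = rep_len(class, length(ids)),
             stringsAsFactors = FALSE)
}

# network straight from edge vectors over an all-TF universe
tiny_network <- function(regulator, target, ids = NULL) {
  ids <- ids %||% sort(unique(c(regulator, target)))
  if (length(regulator)) {
    build_network(interaction_table(regulator, target), make_universe(ids))
  } else {
    build_network(list(), make_universe(ids))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded Erdos-Renyi directed graph over n all-TF nodes
random_graph <- function(seed, n, p) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  tiny_network(ids[pairs$from[keep]], ids[pairs$to[keep]], ids = ids)
}

# expression matrix with dimnames
expr_matrix <- function(values, features, samples) {
  matrix(values, nrow = length(features),
         dimnames = list(features, samples))
}

random_expr <- function(seed, n_feat, n_samp, prefix = "F") {
  set.seed(seed)
  expr_matrix(stats::rnorm(n_feat * n_samp),
              sprintf("%s%03d", prefix, seq_len(n_feat)),
              sprintf("S%03d", seq_len(n_samp)))
}

# block-diagonal similarity: `sizes` blocks with high within / low across
block_similarity <- function(sizes, within = 1, across = 0, noise = 0,
                             seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  W <- matrix(across, n, n)
  W[outer(lab, lab, "==")] <- within
  if (noise > 0) {
    set.seed(seed)
    E <- matrix(stats::runif(n * n, 0, noise), n, n)
    W <- W + (E + t(E)) / 2
  }
  diag(W) <- within
  dimnames(W) <- list(sprintf("S%03d", 1:n), sprintf("S%03d", 1:n))
  attr(W, "labels") <- lab
  W
}

# independent log-rank oracle: O/E/V tabulation over distinct event times,
# chi-square = (O-E)' V^{-1} (O-E) on the first k-1 groups
logrank_oracle <- function(time, event, group) {
  group <- as.integer(factor(group))
  k <- max(group)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    n_g <- vapply(1:k, function(g) sum(at_risk & group == g), numeric(1))
    d_g <- vapply(1:k, function(g) sum(event == 1 & time == t & group == g),
                  numeric(1))
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      frac <- d_t * (n_t - d_t) / (n_t - 1)
      for (a in 1:k) {
        for (b in 1:k) {
          V[a, b] <- V[a, b] +
            frac * (n_g[a] / n_t) * ((a == b) - n_g[b] / n_t)
        }
      }
    }
  }
  idx <- seq_len(k - 1)
  z <- (O - E)[idx]
  stat <- as.numeric(t(z) %*% solve(V[idx, idx, drop = FALSE]) %*% z)
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# dense-loop reference for the cross-network diffusion, coded with explicit
# scalar loops and independent of the package's matrix-operation path
snf_fuse_oracle <- function(Ps, Ss, t) {
  m <- length(Ps)
  n <- nrow(Ps[[1]])
  renorm <- function(P) {
    out <- matrix(0, n, n)
    for (i in 1:n) {
      rs <- 0
      for (j in 1:n) if (j != i) rs <- rs + P[i, j]
      if (rs == 0) rs <- .Machine$double.eps
      for (j in 1:n) out[i, j] <- if (i == j) 0.5 else P[i, j] / (2 * rs)
    }
    out
  }
  for (iter in seq_len(t)) {
    new_Ps <- vector("list", m)
    for (v in 1:m) {
      avg <- matrix(0, n, n)
      for (w in setdiff(1:m, v)) avg <- avg + Ps[[w]] / (m - 1)
      P <- Ss[[v]] %*% avg %*% t(Ss[[v]])
      P <- renorm(P)
      new_Ps[[v]] <- (P + t(P)) / 2
    }
    Ps <- new_Ps
  }
  fused <- Reduce(`+`, Ps) / m
  (fused + t(fused)) / 2
}
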