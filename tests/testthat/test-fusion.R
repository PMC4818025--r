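test_that("weighted distance reduces to scaled Euclidean under uniform weights", {
  set.seed(17)
  for (i in 1:5) {
    p <- sample(3:30, 1)
    n <- sample(4:12, 1)
    view <- random_expr(i, p, n)
    D <- weighted_distance_matrix(view, rep(1 / p, p), standardize = FALSE)
    D_ref <- as.matrix(dist(t(view))) / sqrt(p)
    expect_lt(max(abs(D - D_ref)), 1e-12)
  }
})

test_that("weighted distance matches hand arithmetic and handles errors", {
  view <- expr_matrix(c(0, 0, 2, 2), c("f1", "f2"), c("x", "y"))
  D <- weighted_distance_matrix(view, c(f1 = 0.5, f2 = 0.5),
                                standardize = FALSE)
  expect_equal(D["x", "y"], 2)  # sqrt(0.5*4 + 0.5*4)
  expect_equal(diag(D), c(x = 0, y = 0))

  same <- expr_matrix(c(1, 2, 1, 2), c("f1", "f2"), c("x", "y"))
  D2 <- weighted_distance_matrix(same, c(f1 = 1, f2 = 1),
                                 standardize = FALSE)
  expect_equal(D2["x", "y"], 0)

  expect_error(weighted_distance_matrix(view, c(f1 = 0.5)),
               class = "wsnf_domain_error")
  expect_error(weighted_distance_matrix(view[, 1, drop = FALSE],
                                        c(f1 = 1, f2 = 1)),
               class = "wsnf_domain_error")
})

test_that("weighted distances are metrics", {
  set.seed(23)
  view <- random_expr(23, 20, 15)
  w <- setNames(normalize_simplex(runif(20)), rownames(view))
  D <- weighted_distance_matrix(view, w)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (rep in 1:50) {
    ijk <- sample(15, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("affinity kernels match a scalar hand evaluation", {
  # 4 samples on a line; K = 2, mu = 0.5
  x <- c(0, 1, 3, 7)
  D <- abs(outer(x, x, "-"))
  dimnames(D) <- list(paste0("S", 1:4), paste0("S", 1:4))
  aff <- affinity_matrix(D, K = 2, mu = 0.5)

  knn_mean <- sapply(1:4, function(i) mean(sort(D[i, -i])[1:2]))
  for (i in 1:4) {
    for (j in 1:4) {
      eps <- (knn_mean[i] + knn_mean[j] + D[i, j]) / 3
      expect_equal(aff$kernel[i, j], exp(-D[i, j]^2 / (0.5 * eps)),
                   tolerance = 1e-12, info = paste(i, j))
    }
  }
  expect_true(all(diag(aff$kernel) == 1))  # exp(0) on the diagonal
  expect_equal(unname(rowSums(aff$P)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(diag(aff$P)), rep(0.5, 4))
  # S rows: support on the K nearest neighbours only, each row sums to 1
  expect_equal(unname(rowSums(aff$S)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(rowSums(aff$S > 0)), rep(2, 4))
  expect_true(all(diag(aff$S) == 0))

  expect_error(affinity_matrix(D, K = 4), class = "wsnf_domain_error")
})

test_that("duplicate-heavy distance matrices trigger the bandwidth guard", {
  D <- matrix(0, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  expect_warning(aff <- affinity_matrix(D, K = 2, mu = 0.5),
                 "bandwidth")
  expect_true(all(is.finite(aff$P)))
})

test_that("a single view fuses to its symmetrised transition matrix", {
  view <- random_expr(3, 10, 12)
  D <- weighted_distance_matrix(view, rep(0.1, 10))
  aff <- affinity_matrix(D, K = 4, mu = 0.5)
  fused <- snf_fuse(list(aff), t = 20)
  expect_equal(unclass(fused), (aff$P + t(aff$P)) / 2,
               ignore_attr = TRUE)
  expect_equal(attr(fused, "iterations"), 0L)
})

test_that("diffusion matches the independent dense-loop reference", {
  view <- random_expr(9, 15, 20)
  D <- weighted_distance_matrix(view, rep(1 / 15, 15))
  aff <- affinity_matrix(D, K = 5, mu = 0.5)
  for (t_iter in c(1L, 5L)) {
    fused <- snf_fuse(list(aff, aff), t = t_iter)
    ref <- snf_fuse_oracle(list(aff$P, aff$P), list(aff$S, aff$S), t_iter)
    expect_lt(max(abs(unclass(fused) - ref)), 1e-6)
  }
})

test_that("fusion preserves symmetry and nonnegativity at every iteration", {
  v1 <- random_expr(11, 12, 18)
  v2 <- random_expr(12, 8, 18)
  colnames(v2) <- colnames(v1)
  affs <- lapply(list(v1, v2), function(v) {
    affinity_matrix(weighted_distance_matrix(v, rep(1 / nrow(v), nrow(v))),
                    K = 5, mu = 0.5)
  })
  fused <- snf_fuse(affs, t = 6, keep_history = TRUE)
  for (Ps in attr(fused, "history")) {
    for (P in Ps) {
      expect_lt(max(abs(P - t(P))), 1e-12)
      expect_true(all(P >= 0))
      expect_true(all(is.finite(P)))
    }
  }
  expect_equal(unclass(fused), t(unclass(fused)))
})

test_that("fusion rejects mismatched sample sets and empty view lists", {
  v1 <- random_expr(11, 10, 8)
  v2 <- random_expr(12, 10, 8)
  colnames(v2) <- rev(colnames(v1))
  a1 <- affinity_matrix(weighted_distance_matrix(v1, rep(0.1, 10)), 3, 0.5)
  a2 <- affinity_matrix(weighted_distance_matrix(v2, rep(0.1, 10)), 3, 0.5)
  expect_error(snf_fuse(list(a1, a2)), class = "wsnf_domain_error")
  expect_error(snf_fuse(list()), class = "wsnf_domain_error")
})

test_that("two views with shared block structure keep within-block dominance", {
  set.seed(61)
  lab <- rep(1:2, each = 10)
  make_view <- function(seed, p) {
    set.seed(seed)
    base <- matrix(rnorm(p * 20, sd = 0.3), p, 20)
    base[, lab == 2] <- base[, lab == 2] + 3
    dimnames(base) <- list(sprintf("F%02d", 1:p), sprintf("S%02d", 1:20))
    base
  }
  affs <- lapply(list(make_view(1, 12), make_view(2, 9)), function(v) {
    affinity_matrix(weighted_distance_matrix(v, rep(1 / nrow(v), nrow(v))),
                    K = 5, mu = 0.5)
  })
  fused <- unclass(snf_fuse(affs, t = 20))
  diag(fused) <- 0
  for (i in 1:20) {
    within <- sum(fused[i, lab == lab[i]])
    across <- sum(fused[i, lab != lab[i]])
    expect_gt(within, across)
  }
})

test_that("eigengap analysis recovers planted block counts", {
  W3 <- block_similarity(c(5, 6, 7))
  est <- estimate_num_clusters(W3, 2, 10)
  expect_equal(est$k[1], 3)
  expect_equal(attr(est, "n_components"), 3)

  W5 <- block_similarity(rep(8, 5), within = 1, across = 0,
                         noise = 0.05, seed = 4)
  est5 <- estimate_num_clusters(W5, 2, 10)
  expect_equal(est5$k[1], 5)

  # structureless similarity still returns a full ranking
  Wu <- matrix(1, 12, 12, dimnames = list(paste0("S", 1:12),
                                          paste0("S", 1:12)))
  estu <- estimate_num_clusters(Wu, 2, 6)
  expect_equal(sort(estu$k), 2:6)

  expect_error(estimate_num_clusters(W3, 1, 5), class = "wsnf_domain_error")
})

test_that("spectral clustering separates exact blocks and is seed-deterministic", {
  W <- block_similarity(c(8, 9))
  truth <- attr(W, "labels")
  a1 <- spectral_cluster(W, k = 2, seed = 3)
  expect_equal(adjusted_rand_index(a1$cluster, truth), 1)
  a2 <- spectral_cluster(W, k = 2, seed = 3)
  expect_identical(a1, a2)
  expect_equal(sort(unique(a1$cluster)), 1:2)
  expect_error(spectral_cluster(W, k = 17), class = "wsnf_domain_error")
})
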