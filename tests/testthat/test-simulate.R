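small_cfg <- function(seed = 1, ...) {
  defaults <- list(n_mirna = 12, n_tf = 15, n_mrna = 60, n_samples = 36,
                   k_subtypes = 3, n_signal = 8,
                   edge_density = list(
                     "miRNA->mRNA" = 0.04, "miRNA->TF" = 0.02,
                     "TF->miRNA" = 0.01, "TF->mRNA" = 0.04,
                     "TF->TF" = 0.02, "mRNA->mRNA" = 0.01),
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

test_that("all three generators are bitwise deterministic in the seed", {
  cfg <- small_cfg(seed = 14)
  n1 <- simulate_network(cfg)
  n2 <- simulate_network(cfg)
  expect_identical(n1$edges, n2$edges)

  e1 <- simulate_expression(n1, cfg)
  e2 <- simulate_expression(n2, cfg)
  expect_identical(e1$gene_expr, e2$gene_expr)
  expect_identical(e1$mirna_expr, e2$mirna_expr)
  expect_identical(e1$truth$cluster, e2$truth$cluster)

  s1 <- simulate_survival(e1$truth, cfg)
  s2 <- simulate_survival(e2$truth, cfg)
  expect_identical(s1, s2)

  # and a different seed changes the data
  n3 <- simulate_network(small_cfg(seed = 15))
  expect_false(identical(n1$edges, n3$edges))
})

test_that("generated networks satisfy the consuming modules' invariants", {
  cfg <- small_cfg(seed = 2)
  net <- simulate_network(cfg)
  expect_s3_class(net, "regulatory_network")
  expect_true(all(net$edges$regulator != net$edges$target))
  expect_false(any(duplicated(paste(net$edges$regulator, net$edges$target))))
  # class-consistent directions only
  klass <- setNames(net$nodes$class, net$nodes$feature)
  for (i in seq_len(nrow(net$edges))) {
    r <- klass[[net$edges$regulator[i]]]
    t <- klass[[net$edges$target[i]]]
    expect_true(t %in% wsnf:::ALLOWED_INTERACTIONS[[r]])
  }
})

test_that("zero densities give isolated nodes only", {
  cfg <- small_cfg(edge_density = list("miRNA->mRNA" = 0, "miRNA->TF" = 0,
                                       "TF->miRNA" = 0, "TF->mRNA" = 0,
                                       "TF->TF" = 0, "mRNA->mRNA" = 0),
                   signal_placement = "isolated")
  net <- simulate_network(cfg)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(network_size(net), 87L)
  expect_error(simulate_network(small_cfg(edge_density = list(
    "miRNA->mRNA" = 1.5))), class = "wsnf_domain_error")
})

test_that("hub exponent skews the out-degree distribution", {
  share_top_decile <- function(hub_exponent, seed) {
    cfg <- small_cfg(seed = seed, hub_exponent = hub_exponent)
    deg <- wsnf:::node_degrees(simulate_network(cfg))$out_degree
    deg <- sort(deg, decreasing = TRUE)
    sum(deg[seq_len(ceiling(length(deg) / 10))]) / sum(deg)
  }
  shares_skewed <- vapply(1:20, function(s) share_top_decile(2, s), numeric(1))
  shares_flat <- vapply(1:20, function(s) share_top_decile(0, s), numeric(1))
  expect_gt(mean(shares_skewed), mean(shares_flat))
})

test_that("planted signal lands on the requested feature pool", {
  cfg <- small_cfg(seed = 6)
  net <- simulate_network(cfg)
  expr <- simulate_expression(net, cfg)
  sets <- expr$signal_sets
  expect_length(sets, 3L)
  expect_length(unique(unlist(sets)), 3L * cfg$n_signal)  # disjoint
  # network-central: signal features are hubs or their targets, and the
  # top-out-degree regulator is among them
  deg <- wsnf:::node_degrees(net)
  top <- names(which.max(deg$out_degree))
  expect_true(top %in% unlist(sets))

  # mean shift is present where planted and absent elsewhere
  all_expr <- rbind(expr$gene_expr, expr$mirna_expr)
  lab <- expr$truth$cluster
  f <- sets[[2]][1]
  expect_gt(mean(all_expr[f, lab == 2]) - mean(all_expr[f, lab != 2]), 0.5)

  # isolated placement with too small a pool errors: 87 isolated features
  # cannot host 3 x 30 disjoint signal sets
  cfg_iso <- small_cfg(seed = 6, signal_placement = "isolated",
                       n_signal = 30,
                       edge_density = list("miRNA->mRNA" = 0, "miRNA->TF" = 0,
                                           "TF->miRNA" = 0, "TF->mRNA" = 0,
                                           "TF->TF" = 0, "mRNA->mRNA" = 0))
  expect_error(simulate_expression(simulate_network(cfg_iso), cfg_iso),
               class = "wsnf_domain_error")
})

test_that("effect size zero removes recoverable subtype structure", {
  aris <- vapply(1:10, function(seed) {
    cfg <- small_cfg(seed = seed, effect_size = 0)
    net <- simulate_network(cfg)
    expr <- simulate_expression(net, cfg)
    res <- run_wsnf(expr$gene_expr, expr$mirna_expr, net, k = 3,
                    K = 10, seed = seed)
    adjusted_rand_index(res$assignment, expr$truth)
  }, numeric(1))
  expect_lt(abs(median(aris)), 0.1)
})

test_that("survival times follow the configured hazards and censoring", {
  cfg <- small_cfg(seed = 30, n_samples = 300, censor_rate = 0)
  lab <- data.frame(sample = sprintf("S%03d", 1:300),
                    cluster = rep(1:3, each = 100))
  class(lab) <- c("subtype_assignment", "data.frame")
  surv <- simulate_survival(lab, cfg)
  expect_true(all(surv$event == 1L))
  # exponential means ~ 1/hazard per subtype
  for (g in 1:3) {
    expect_equal(mean(surv$time[lab$cluster == g]), 1 / cfg$hazards[g],
                 tolerance = 0.35)
  }

  cfg2 <- small_cfg(seed = 31, n_samples = 300, censor_rate = 0.3)
  surv2 <- simulate_survival(lab, cfg2)
  expect_equal(mean(surv2$event == 0), 0.3, tolerance = 0.2)

  lab$cluster[1] <- 9
  expect_error(simulate_survival(lab, cfg), class = "wsnf_domain_error")
})

test_that("fixtures round-trip through the TSV writers losslessly", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 44)
  write_fixture(cfg, dir)
  net <- simulate_network(cfg)
  expr <- simulate_expression(net, cfg)

  genes_rt <- read_expression(file.path(dir, "genes.tsv"))
  expect_equal(genes_rt, expr$gene_expr, tolerance = 1e-12)
  mirna_rt <- read_expression(file.path(dir, "mirna.tsv"))
  expect_equal(mirna_rt, expr$mirna_expr, tolerance = 1e-12)

  classes_rt <- read_feature_classes(file.path(dir, "classes.tsv"))
  tab <- load_interactions(file.path(dir, "edges.tsv"))
  net_rt <- build_network(tab, classes_rt)
  expect_equal(net_rt$edges[, c("regulator", "target")],
               net$edges[, c("regulator", "target")])

  surv_rt <- read_survival(file.path(dir, "survival.csv"))
  surv <- simulate_survival(expr$truth, cfg)
  expect_equal(surv_rt$time, surv$time, tolerance = 1e-12)
  expect_identical(surv_rt$event, surv$event)
})
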