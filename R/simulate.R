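# Seeded generators for regulatory networks, two-view expression matrices
# with planted subtypes, and exponential survival outcomes.  These emulate
# the statistical structure the weighting step assumes: discriminative
# features that are also important (high out-degree) regulators.

#' Simulation configuration
#'
#' Default values define the reference study conditions used throughout the
#' test bed: 150 samples in 3 balanced subtypes over 300 mRNAs, 60 TFs and
#' 40 miRNAs, subtype mean shifts of 2 noise SDs placed on network-central
#' features, and exponential survival with hazard ratio 3 between
#' consecutive subtypes under ~20% censoring.
#'
#' @param n_mirna,n_tf,n_mrna Feature counts per class.
#' @param edge_density Named list of densities per interaction class
#'   (fraction of admissible regulator-target pairs realised as edges).
#' @param hub_exponent Out-degree skew: regulator propensities proportional
#'   to `rank^-hub_exponent` (0 = uniform; larger = heavier-tailed hubs).
#' @param n_samples Number of samples (patients).
#' @param k_subtypes Number of planted subtypes (>= 2).
#' @param effect_size Subtype mean shift in units of `noise_sd`.
#' @param signal_placement Where the discriminative features sit:
#'   `"network-central"` (top out-degree regulators and their targets),
#'   `"random"`, or `"isolated"` (degree-zero features).
#' @param n_signal Discriminative features per subtype (disjoint sets).
#' @param noise_sd Baseline expression SD on the log scale.
#' @param hazards Per-subtype exponential hazards (per day); defaults to
#'   `3^(0:(k-1)) / 1500`.
#' @param censor_rate Fraction of records censored, in \[0, 1).
#' @param seed Integer seed; all three generators are deterministic in it.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_mirna = 40L, n_tf = 60L, n_mrna = 300L,
                              edge_density = list(
                                "miRNA->mRNA" = 0.02, "miRNA->TF" = 0.01,
                                "TF->miRNA" = 0.005, "TF->mRNA" = 0.02,
                                "TF->TF" = 0.01, "mRNA->mRNA" = 0.005),
                              hub_exponent = 1,
                              n_samples = 150L, k_subtypes = 3L,
                              effect_size = 2, signal_placement = "network-central",
                              n_signal = 25L, noise_sd = 1,
                              hazards = NULL, censor_rate = 0.2,
                              seed = 1L) {
  stopifnot(n_mirna >= 1L, n_tf >= 1L, n_mrna >= 1L, k_subtypes >= 2L,
            effect_size >= 0, noise_sd > 0, n_signal >= 1L,
            censor_rate >= 0, censor_rate < 1)
  signal_placement <- match.arg(signal_placement,
                                c("network-central", "random", "isolated"))
  if (is.null(hazards)) hazards <- 3^(seq_len(k_subtypes) - 1L) / 1500
  if (length(hazards) != k_subtypes || any(hazards <= 0)) {
    stop_wsnf("need one positive hazard per subtype",
              class = "wsnf_domain_error")
  }
  structure(
    list(n_mirna = as.integer(n_mirna), n_tf = as.integer(n_tf),
         n_mrna = as.integer(n_mrna), edge_density = edge_density,
         hub_exponent = hub_exponent, n_samples = as.integer(n_samples),
         k_subtypes = as.integer(k_subtypes), effect_size = effect_size,
         signal_placement = signal_placement, n_signal = as.integer(n_signal),
         noise_sd = noise_sd, hazards = hazards, censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_feature_ids <- function(cfg) {
  list(miRNA = sprintf("miR-%03d", seq_len(cfg$n_mirna)),
       TF = sprintf("TF%03d", seq_len(cfg$n_tf)),
       mRNA = sprintf("G%04d", seq_len(cfg$n_mrna)))
}

#' Simulate a typed regulatory network
#'
#' Draws class-consistent directed edges (miRNA -> mRNA/TF,
#' TF -> miRNA/mRNA/TF, mRNA -> mRNA) at the configured per-class densities.
#' Regulators are sampled with propensity `rank^-hub_exponent`, producing a
#' heavy-tailed out-degree distribution for positive exponents.  Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg A `sim_config` from [simulation_config()].
#' @return A `regulatory_network` (see [build_network()]).
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_feature_ids(cfg)
  universe <- data.frame(
    feature = unlist(ids, use.names = FALSE),
    class = rep(names(ids), lengths(ids)),
    stringsAsFactors = FALSE
  )
  edges <- with_seed(cfg$seed, {
    out <- list()
    for (cls in names(cfg$edge_density)) {
      parts <- strsplit(cls, "->", fixed = TRUE)[[1L]]
      regs <- ids[[parts[1L]]]
      tgts <- ids[[parts[2L]]]
      within <- parts[1L] == parts[2L]
      n_pairs <- length(regs) * length(tgts) - if (within) length(regs) else 0L
      dens <- cfg$edge_density[[cls]]
      if (dens < 0 || dens > 1) {
        stop_wsnf("edge density for ", cls, " must be in [0, 1]",
                  class = "wsnf_domain_error")
      }
      n_edges <- round(dens * n_pairs)
      if (n_edges == 0L) next
      # enumerate admissible pairs; regulator propensity rank^-hub_exponent
      reg_w <- seq_along(regs)^(-cfg$hub_exponent)
      pair_reg <- rep(seq_along(regs), each = length(tgts))
      pair_tgt <- rep(seq_along(tgts), times = length(regs))
      if (within) {
        keep <- pair_reg != pair_tgt
        pair_reg <- pair_reg[keep]
        pair_tgt <- pair_tgt[keep]
      }
      pick <- sample(length(pair_reg), n_edges, replace = FALSE,
                     prob = reg_w[pair_reg])
      out[[cls]] <- data.frame(regulator = regs[pair_reg[pick]],
                               target = tgts[pair_tgt[pick]],
                               source = "simulated",
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  if (is.null(edges)) {
    edges <- data.frame(regulator = character(), target = character(),
                        source = character(), stringsAsFactors = FALSE)
  }
  attr(edges, "expected_class") <- "any"
  build_network(list(edges), universe)
}

#' Simulate two-view expression data with planted subtypes
#'
#' Baseline values are i.i.d. normal(0, `noise_sd`) on the log scale;
#' samples are partitioned into `k_subtypes` balanced groups, and each
#' subtype's disjoint signal set of `n_signal` features is shifted upward by
#' `effect_size * noise_sd` in that subtype's samples.  Signal sets are
#' taken round-robin from the pool dictated by `signal_placement`:
#' top-out-degree regulators interleaved with their targets
#' (network-central), a uniform permutation (random), or degree-zero
#' features (isolated).
#'
#' @param net A `regulatory_network`, typically from [simulate_network()].
#' @param cfg The matching `sim_config`.
#' @return List with `gene_expr` (TF + mRNA features x samples),
#'   `mirna_expr`, `truth` (a `subtype_assignment` with the planted
#'   labels), `signal_sets` (list of per-subtype feature sets) and
#'   `classes` (feature class table).
#' @export
simulate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "regulatory_network"), inherits(cfg, "sim_config"))
  feats <- net$nodes$feature
  klass <- stats::setNames(net$nodes$class, feats)
  n <- cfg$n_samples
  k <- cfg$k_subtypes
  samples <- sprintf("S%03d", seq_len(n))
  subtype <- rep(seq_len(k), length.out = n)

  deg <- node_degrees(net)
  pool <- switch(
    cfg$signal_placement,
    "network-central" = {
      # regulators by descending out-degree, then their targets in the same
      # order: discriminative features are the high-rank nodes themselves
      hubs <- feats[order(-deg$out_degree, seq_along(feats))]
      hubs <- hubs[deg$out_degree[hubs] > 0]
      tgts <- unlist(lapply(hubs, function(h) {
        net$edges$target[net$edges$regulator == h]
      }))
      unique(c(hubs, tgts))
    },
    "random" = with_seed(cfg$seed + 1L, sample(feats)),
    "isolated" = feats[deg$out_degree == 0L & deg$in_degree == 0L]
  )
  need <- k * cfg$n_signal
  if (length(pool) < need) {
    stop_wsnf("signal pool (", length(pool), " features, placement ",
              cfg$signal_placement, ") smaller than k * n_signal = ", need,
              class = "wsnf_domain_error")
  }
  chosen <- pool[seq_len(need)]
  signal_sets <- split(chosen, rep(seq_len(k), length.out = need))

  X <- with_seed(cfg$seed + 2L, {
    m <- matrix(stats::rnorm(length(feats) * n, 0, cfg$noise_sd),
                nrow = length(feats), ncol = n,
                dimnames = list(feats, samples))
    for (s in seq_len(k)) {
      m[signal_sets[[s]], subtype == s] <-
        m[signal_sets[[s]], subtype == s] + cfg$effect_size * cfg$noise_sd
    }
    m
  })

  truth <- data.frame(sample = samples, cluster = subtype,
                      stringsAsFactors = FALSE)
  attr(truth, "k") <- k
  attr(truth, "seed") <- cfg$seed
  class(truth) <- c("subtype_assignment", "data.frame")

  list(
    gene_expr = X[klass[feats] %in% c("TF", "mRNA"), , drop = FALSE],
    mirna_expr = X[klass[feats] == "miRNA", , drop = FALSE],
    truth = truth,
    signal_sets = signal_sets,
    classes = net$nodes
  )
}

# upper censoring bound b for uniform(0, b) censoring of exp(rate) times
# such that P(censored) = rate_target
uniform_censor_bound <- function(hazard, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(b) (1 - exp(-hazard * b)) / (hazard * b) - censor_rate
  # f decreases from 1 (b -> 0) to 0 (b -> Inf)
  upper <- 1 / hazard
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(1e-8 / hazard, upper), tol = 1e-10)$root
}

#' Simulate survival outcomes for a subtype assignment
#'
#' Event times are exponential with the subtype's hazard; censoring is
#' independent uniform on (0, b) with b chosen per subtype so that the
#' expected censored fraction equals `censor_rate`.
#'
#' @param labels A `subtype_assignment` (sample, cluster).
#' @param cfg A `sim_config` providing `hazards`, `censor_rate`, `seed`;
#'   hazards must cover every subtype present.
#' @return `data.frame` with columns `sample`, `time` (days), `event`.
#' @export
simulate_survival <- function(labels, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lab <- assignment_labels(labels)
  if (max(lab) > length(cfg$hazards)) {
    stop_wsnf("no hazard configured for subtype ", max(lab),
              class = "wsnf_domain_error")
  }
  hz <- cfg$hazards[lab]
  with_seed(cfg$seed + 3L, {
    t_event <- stats::rexp(length(lab), rate = hz)
    if (cfg$censor_rate > 0) {
      bounds <- vapply(cfg$hazards, uniform_censor_bound, numeric(1L),
                       censor_rate = cfg$censor_rate)
      t_cens <- stats::runif(length(lab), 0, bounds[lab])
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, length(lab))
      time <- t_event
    }
    data.frame(sample = labels$sample, time = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits `genes.tsv`, `mirna.tsv`, `edges.tsv`, `classes.tsv`,
#' `survival.csv` and `truth_labels.tsv` under `dir`.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- simulate_network(cfg)
  expr <- simulate_expression(net, cfg)
  surv <- simulate_survival(expr$truth, cfg)
  write_expression(expr$gene_expr, file.path(dir, "genes.tsv"))
  write_expression(expr$mirna_expr, file.path(dir, "mirna.tsv"))
  utils::write.table(net$edges[, c("regulator", "target")],
                     file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, file.path(dir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(surv, file.path(dir, "survival.csv"), row.names = FALSE)
  utils::write.table(expr$truth, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
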