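# wsnf — weighted similarity network fusion for cancer subtype discovery

Clustering patients into molecular subtypes from multi-omics expression
data usually treats every measured feature as equally informative. `wsnf`
instead weights each feature — mRNA, transcription factor (TF) or miRNA —
by its importance in the miRNA-TF-mRNA regulatory circuitry before fusing
per-data-type patient similarity networks and clustering the fused
network. It is aimed at computational biologists who have matched gene and
miRNA expression matrices for a patient cohort, a directed regulatory
edge list exported from interaction databases, and (optionally) survival
follow-up to validate the resulting subtypes.

## Method

1. **Regulatory rank** (`rank_features`). On the directed regulatory graph
   every feature gets a PageRank-style score with the orientation
   reversed — rank flows from targets back to regulators:

   R(fᵢ) = (1−d)/N + d · Σ_{fⱼ ∈ T(fᵢ)} R(fⱼ)/L(fⱼ)

   with T(fᵢ) the targets of fᵢ, L(fⱼ) the number of regulators of fⱼ and
   damping d (default 0.85). The recursion is implemented literally: mass
   reaching target-free features is not redistributed, so Σ R ≤ 1.

2. **Feature weights** (`feature_weights`). Expression variation is the
   raw median absolute deviation per feature across samples. Ranks and
   MADs are normalised to the simplex (RN, MADN) and combined as

   W(fᵢ) = β·RN(fᵢ) + (1−β)·MADN(fᵢ),  β = 0.8 by default.

3. **Weighted fusion + clustering** (`run_wsnf`). Per view, patient
   distances are the weighted Euclidean metric
   √(Σ_m W(f_m)(f_m^{Sᵢ} − f_m^{Sⱼ})²); a locally adaptive Gaussian
   kernel turns them into affinities, the views are merged by iterative
   cross-network diffusion, and the fused similarity is partitioned by
   normalized spectral clustering (k given, or chosen by the Laplacian
   eigengap).

4. **Validation** (`silhouette_from_similarity`, `core_samples`,
   `logrank_test`, `adjusted_rand_index`). Silhouette widths on the fused
   network, core-sample extraction (drop negative widths), k-group
   log-rank survival separation, and ARI against known labels for
   synthetic runs.

Seeded generators (`simulate_network`, `simulate_expression`,
`simulate_survival`) produce a complete synthetic test bed: a typed
regulatory graph with hub-skewed out-degrees, two expression views with
subtype mean shifts planted on network-central features, and exponential
survival with subtype-dependent hazards.

## Worked example

```r
library(wsnf)

cfg  <- simulation_config(seed = 42)        # 150 samples, 3 subtypes, 400 features
net  <- simulate_network(cfg)
expr <- simulate_expression(net, cfg)

res <- run_wsnf(expr$gene_expr, expr$mirna_expr, net, k = 3, seed = 42)
res
#> weighted similarity network fusion result
#>   150 samples, k = 3 subtypes (beta = 0.8, K = 20, mu = 0.5, t = 20, seed = 42)
#> subtype
#>  1  2  3
#> 50 50 50

adjusted_rand_index(res$assignment, expr$truth)
#> [1] 1

silhouette_from_similarity(res$fused, res$assignment)
#> silhouette over 150 samples in 3 clusters; average width 0.7307

surv <- simulate_survival(expr$truth, cfg)
lr   <- logrank_test(surv, res$assignment)
sprintf("chi-square %.2f on %d df, p = %.3g", lr$statistic, lr$df, lr$p_value)
#> [1] "chi-square 48.13 on 2 df, p = 3.54e-11"

head(res$weights[order(-res$weights$W), c("feature", "class", "rank", "W")], 3)
#>     feature class       rank          W
#> 41    TF001    TF 0.02103463 0.04785935
#> 1   miR-001 miRNA 0.01261050 0.02896475
#> 6   miR-006 miRNA 0.01193254 0.02746812
```

The assignment recovers the planted partition exactly (ARI 1), the fused
network is internally consistent (average silhouette 0.73, all samples
core), the identified subtypes separate survival sharply, and the heaviest
weights land on the hub regulators carrying the planted signal.

A command-line front end over the same functions lives at
`inst/cli/wsnf.R`:

```sh
Rscript inst/cli/wsnf.R run --gene-expr genes.tsv --mirna-expr mirna.tsv \
  --network edges.tsv --classes classes.tsv --beta 0.8 --k auto --seed 17 --out results/
```

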