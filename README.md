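# chronet

Succession-stage detection and co-occurrence network analysis for
microbiome chronosequences.

Ecological restoration is usually monitored as a smooth trajectory, but
soil bacterial and fungal communities along a restoration
chronosequence (degraded control, a ladder of restoration ages, and a
non-degraded reference, sampled with replication) often occupy a small
number of discrete regimes instead: an early **Chaos** stage —
fragmented, weakly modular co-occurrence structure, almost no negative
associations — and a late **Recovery** stage — dense, strongly modular
networks with keystone taxa and a much larger share of competitive
(negative) links. chronet is a tidyverse-style R package for detecting
those stages from OTU count tables and quantifying how deterministic
and how fragile each stage's interaction structure is.

The chain it implements:

* **Compositional groundwork** — relative abundance; centered log-ratio
  transform `clr_i = ln(x_i + c) − mean_j ln(x_j + c)`; Aitchison
  distance of every sample to the non-degraded reference centroid
  (compositional convergence).
* **Diversity** — observed richness, Chao1, Shannon, Gini–Simpson;
  Kruskal–Wallis + Dunn/BH with compact letter displays; Bray–Curtis
  `BC(x,y) = Σ|x_i−y_i| / Σ(x_i+y_i)`, PCoA, PERMANOVA and ANOSIM with
  seeded permutation p-values.
* **Consensus stages** — Ward clustering on Bray–Curtis and k-means on
  PCoA coordinates, silhouette-selected k (2–6); samples are Core only
  when both routes agree, otherwise Ambiguous; stage identity assigned
  by reference convergence or by network topology.
* **Supervised validation** — 100-tree random forest, stratified 5-fold
  cross-validation, out-of-fold AUC, cumulative confusion matrix, Gini
  importance biomarker ranking.
* **Networks** — per-stage core OTUs (prevalence > 50%, mean relative
  abundance > 0.01%), Spearman |ρ| > 0.7 with BH q < 0.01, signed
  edges; Louvain modules; Zi–Pi keystone roles (thresholds 2.5 / 0.62);
  Erdős–Rényi G(N, M) null-model modularity Z-score
  `Z = (Q_obs − Q̄_rand)/σ_rand` over a 100-graph ensemble.
* **Robustness** — random failure (averaged over 50 runs), degree
  attack, and keystone attack (NetworkHub > ModuleHub > Connector >
  Peripheral, degree tie-break), tracking the relative largest
  connected component and its collapse threshold.

A synthetic chronosequence generator (Gaussian copula over planted
correlation modules, multinomial counts) reproduces the study design —
55 samples = 11 groups × 5 replicates, two latent regimes, planted
modules, hubs and negative-edge fractions — so the whole pipeline is
testable against known ground truth.

## Worked example

```r
library(chronet)

gen <- generate_chronosequence(seed = 42)   # 55 samples, 120 OTUs
bc  <- bray_curtis_matrix(relative_abundance(gen$table))
ord <- pcoa_ordination(bc)
silhouette_scan(bc, ord, seed = 42)
#> # A tibble: 5 × 3
#>       k hierarchical kmeans
#>   <int>        <dbl>  <dbl>
#> 1     2       0.286  0.279
#> 2     3       0.145  0.167
#> 3     4       0.146  0.145
#> 4     5       0.0874 0.0903
#> 5     6       0.0788 0.0764
#> best k: hierarchical=2, kmeans=2
```

Both clustering routes peak at k = 2: the chronosequence resolves into
two regimes. Consensus assignment, identity labeling by convergence to
the reference, and supervised validation:

```r
ca   <- consensus_cluster(bc, ord, k = 2, seed = 42)
conv <- convergence_to_reference(clr_transform(gen$table),
                                 gen$table$metadata)
lab  <- label_stages(ca, convergence = conv)
table(lab$core_stage)
#>    Chaos Recovery
#>       20       35

stages <- setNames(lab$core_stage, lab$sample_id)
crossval_classify(gen$table, stages, seed = 42)
#> Stratified 5-fold CV: mean AUC = 1 +/- 0 (n = 55)
#>           predicted
#> truth      Chaos Recovery
#>   Chaos       20        0
#>   Recovery     0       35
```

Every sample lands in a Core stage (none Ambiguous), the 20 early
samples are Chaos, and a cross-validated random forest separates the
stages perfectly (AUC 1.0) — the regimes are real, not clustering
artifacts. The Recovery-stage network and its null-model determinism:

```r
rec <- lab$sample_id[lab$core_stage == "Recovery"]
net <- build_network(correlation_edges(
         filter_core_otus(subset_otu_table(gen$table, samples = rec))))
edge_sign_summary(net)
#>   positive_edges negative_edges total_edges negative_proportion negative_percent
#> 1             89             25         114               0.219             21.9

part <- louvain_partition(net, seed = 42)
modularity_zscore(net, seed = 42, partition = part)
#> Modularity Z-score: Q_obs = 0.8199 , null 0.3794 +/- 0.01561 -> Z = 28.22
```

21.9% of recovered edges are negative (the generator planted 30% at
the latent level; attenuation is expected), and the observed modularity
sits 28 standard deviations above the Erdős–Rényi baseline — a strongly
deterministic topology. Keystone fragility on the planted recovery
graph:

```r
pn <- planted_network(gen$truth, "recovery", seed = 42)
collapse_threshold(simulate_attack(pn, "keystone",
                                   roles = planted_roles(pn)))
#>   level fraction_removed crossed
#> 1   0.5            0.187 TRUE
collapse_threshold(simulate_attack(pn, "random", seed = 42))
#>   level fraction_removed crossed
#> 1   0.5            0.475 TRUE
```

Removing keystones collapses the network after ~19% of nodes are gone;
random loss needs ~48% — the recovery-stage topology is robust to
stochastic extinction but critically dependent on its hubs and
connectors.

`run_pipeline(table, pipeline_config(seed = 1), out_dir = "out/")` runs
the whole chain per kingdom and writes every table plus a seeded,
content-hashed manifest; `autoplot()` / `plot_*()` helpers cover the
standard figures (ordination, silhouette profile, Zi–Pi plane,
robustness curves, stage composition).

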