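---
title: "Detecting succession stages and quantifying network determinism in microbiome chronosequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting succession stages and quantifying network determinism in microbiome chronosequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronet)
library(dplyr)
```

## The analytical problem

Restoration chronosequences substitute space for time: plots restored 1,
4, ..., 18 years ago are sampled simultaneously, together with a severely
degraded control (SD) and a non-degraded reference (ND), and each
community is profiled as an OTU count table. chronet asks two questions
of such data. First, does the continuous chronosequence hide a small
number of discrete community regimes — an early, weakly organised
"Chaos" state and a late, densely organised "Recovery" state — and can
samples be assigned to them without circular reliance on their age?
Second, once stages exist, how deterministic and how fragile is the
co-occurrence structure within each stage?

The package implements the full chain: compositional transforms, alpha
and beta diversity with the standard non-parametric tests, consensus
stage detection, supervised validation, stage-wise network inference,
null-model topology, keystone classification, and attack simulations.
Every step consumes and produces plain tables (tibbles or TSV files), so
the chain is scriptable end to end; `run_pipeline()` wires it together.

## Stage detection by consensus

Community dissimilarity is Bray–Curtis on relative abundances,
\(BC(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)\). Two deliberately
different clusterers are run: Ward-linkage agglomeration directly on the
dissimilarity matrix, and k-means on the principal-coordinate (classical
scaling) embedding. The number of clusters is chosen by the mean
silhouette width over k = 2..6, separately per route. k-means labels are
aligned to the hierarchical labels by maximum-agreement matching over
all k! relabelings; a sample is a *Core* member of a stage only when the
two routes agree, otherwise it is *Ambiguous* and excluded from every
stage-conditioned analysis downstream.

Two details are genuinely open choices and are set as follows. Ward
linkage is applied to the raw Bray–Curtis values (`ward.D2`), although
Bray–Curtis is not Euclidean; a `sqrt_dist` flag provides the
square-root transform that makes the dissimilarity metric. K-means
consumes all positive-eigenvalue ordination axes by default (an `axes`
argument restricts it) with 10 seeded restarts, best inertia kept.

Stage *identity* is assigned by one of two rules. The default
`"convergence"` rule computes, per core cluster, the mean Aitchison
distance (Euclidean distance between CLR-transformed compositions,
\(clr_i = \ln(x_i + c) - \overline{\ln(x + c)}\), pseudocount c = 1 on
counts by default) to the centroid of the ND reference group; the closer
cluster is Recovery. The `"topology"` rule instead builds a network per
cluster and calls the cluster with the higher modularity Z-score
Recovery, defining identity purely by network organisation; it is the
rule to prefer when a reference group is absent or suspect, at the cost
of two extra network builds. A tie in either criterion raises an error
directing the user to the other rule.

The stages are validated supervised: a 100-tree random forest on
relative abundances under stratified 5-fold cross-validation, scored by
out-of-fold AUC and a cumulative confusion matrix (0.5 threshold), with
Gini importance ranking the discriminating OTUs.

## Stage-wise networks and their null model

Within each stage, core OTUs are those present in strictly more than
50% of the stage's samples with mean relative abundance strictly above
0.01% — both inequalities strict, so values exactly at a threshold are
excluded. Edges are Spearman correlations with |rho| > 0.7 and
Benjamini–Hochberg q < 0.01, the BH family being all pairs of that
stage's core OTUs jointly. Correlations use average ranks; p-values come
from the t approximation, except at n <= 7 samples where an exact
permutation tail over all n! rank permutations is affordable and is
used instead. Constant OTUs have no defined rank correlation and are
skipped with a message. Correlations are computed on relative
abundances by default (`on = "counts"` is available; Spearman ranks make
the difference minor). Node sets contain edge-incident OTUs by default
(`include_isolated = TRUE` keeps the full core set), matching the usual
reporting convention for node counts.

Modules come from Louvain detection on the unweighted, unsigned
skeleton — sign encodes interaction quality, not interaction absence, so
it is deliberately ignored for community detection — with 10 seeded
restarts, best Newman Q kept. Per node, the within-module degree
z-score Zi and participation coefficient
\(P_i = 1 - \sum_s (k_{is}/k_i)^2\) classify roles by the conventional
boxes: Peripheral (Zi <= 2.5, Pi <= 0.62), Connector (Zi <= 2.5,
Pi > 0.62), ModuleHub (Zi > 2.5, Pi <= 0.62), NetworkHub (both
exceeded). Degenerate cases are pinned down explicitly: a module whose
within-degrees have zero spread gives Zi = 0 for its members, and an
isolated node has Pi = 0 and is Peripheral.

Topological determinism is the Erdős–Rényi G(N, M) modularity Z-score
\(Z = (Q_{obs} - \bar Q_{rand}) / \sigma_{rand}\) over an ensemble of
100 random graphs with exactly the observed node and edge counts, each
partitioned with the *same* Louvain settings and fresh seeds derived
from the master seed. Re-running detection per null graph (rather than
scoring a fixed partition) is the conservative choice: it compares
best-found modularity against best-found modularity. A zero ensemble
spread yields an infinite-Z sentinel with a warning. Self-calibration
holds by construction: feeding a G(N, M) draw back in gives |Z| <= 3 in
at least 95% of seeds (tested).

## Robustness simulations

Nodes are removed one at a time and the relative size of the largest
connected component (denominator: the original node count) is recorded
after every removal. Three orders are implemented: uniformly random
(mean over 50 repetitions by default, per-repetition curves retained),
descending initial degree, and keystone priority (NetworkHub >
ModuleHub > Connector > Peripheral, degree then id as tie-breaks).
Orders are static by default — fixed from the intact network — with an
adaptive recomputing variant behind a flag. The collapse threshold is
read off the piecewise-linear interpolation of the recorded curve as
the smallest removed fraction at which it falls below a stated level
(default 0.5); a curve that never crosses reports 1.0 with a flag. On a
10-clique the random-failure curve is exactly 1 − f and the threshold
is exactly 0.5; on a 10-node star the degree attack drops the curve to
0.1 in one removal, and the interpolated threshold lands inside that
first segment (5/90 ≈ 0.056).

## The synthetic chronosequence generator

The paper-scale data cannot ship with a package, and no generative model
is implied by real data anyway, so the generator is a first-class,
tested module whose defaults *are* the study conditions: 55 samples =
11 groups × 5 replicates, two latent regimes, 120 OTUs, 20,000 counts
per sample. Counts arise from a Gaussian copula: per regime, a factor
model plants modules as correlation blocks (members load \(\sqrt r\) on
their module factor, with a per-block subset of loadings negated to hit
a target negative-association fraction exactly in expectation),
idiosyncratic noise attenuates realised correlations by
\(1/(1+\sigma^2)\), group means shift along a fixed contrast axis
(step between regimes plus a mild within-regime ramp so later groups
sit closer to the reference), and latent values map monotonically
through a softmax of log-weights to multinomial count draws. Monotone
mapping is the point: Spearman-based inference downstream sees exactly
the planted rank-correlation structure, which Dirichlet-multinomial
alternatives cannot control as directly.

Defaults encode the intended contrast. Chaos: 4 modules of 8, latent
within-module correlation 0.85 under observation noise 0.35 (realised
≈ 0.63, mostly below the 0.7 edge rule — hence sparse, near-empty,
almost all-positive networks). Recovery: 6 modules of 8, correlation
0.9 under noise 0.2 (realised ≈ 0.87 — dense modular networks), 30%
negative associations, plus planted keystones: 4 module hubs, 6
connectors bridging cyclic module triples, 2 network hubs spanning four
modules. The regime split assigns the first four groups (SD–6y) to
chaos, the rest and ND to recovery — 20 vs 35 samples. The centroid
shift (1.5 on the per-OTU log scale) is "strong separation": silhouette
scans pick k = 2 and cross-validated AUC saturates, which is what the
validation targets require.

One limitation is intrinsic and worth stating precisely: with
(near-)orthogonal module factors, a node's squared correlations to
distinct modules sum to at most 1, so no node can correlate above 0.7
with members of three or more modules. Data-recovered networks
therefore cannot contain Pi > 0.62 connectors by construction — exactly
the pattern real sparse networks often show. Graph-level properties of
connectors and hubs (role ordering in attacks, fragility) are instead
tested on `planted_network()`, the explicit noiseless graph the truth
encodes: dense within-module neighbourhoods (edge probability 0.9),
module hubs wired to every module mate, connectors to three members in
each of their three modules, network hubs to four members in each of
four modules.

What passing on synthetic data does *not* show: robustness to real-data
features the copula omits — sequencing-depth variation, zero inflation
beyond the multinomial's, phylogenetic correlation of abundances,
compositional closure effects at low diversity, and reversion events
(late-year samples falling back to chaos) which the generator's default
monotone group layout deliberately excludes.

## Numerical conventions

* Shannon uses natural logarithms; Simpson is reported as Gini–Simpson
  1 − D. Chao1 defaults to the bias-corrected form
  \(S_{obs} + F_1(F_1-1)/(2(F_2+1))\), defined even without doubletons;
  the classic form is a flag. Alpha diversity runs on raw counts
  (rarefaction is out of scope and the estimators are
  depth-sensitive — compare across samples of similar depth).
* PERMANOVA partitions \(\sum_{i<j} d_{ij}^2/n\); ANOSIM uses ranked
  dissimilarities with R normalised by n(n−1)/4. Both use the add-one
  permutation convention p = (1 + #{stat* >= stat}) / (1 + B), so p is
  never 0 and never below 1/(B+1); 999 permutations by default. All
  permutations derive from an explicit seed.
* PCoA drops negative-eigenvalue axes from coordinates, reports the
  eigenvalues, and computes explained proportions over positive
  eigenvalues only; no Lingoes/Cailliez correction.
* Kruskal–Wallis uses the tie-corrected H (H = 0, p = 1 when every
  observation is identical); Dunn's Z uses the pooled tie correction
  and BH adjustment. The compact letter display is built from maximal
  cliques of the non-separation graph at q >= 0.05, so sharing a letter
  always means "not separated", and every non-separated pair shares
  one. Because the KW reference distribution is asymptotic, its
  nominal 5% type-I behaviour is verified at 20 samples per group.
* The modal silhouette k across routes breaks ties toward the smaller
  k (table order); k-means empty clusters are avoided by restarts.
* All simulation sizes used in the test-suite (20 generator seeds for
  the k-selection check, 40 seeds for null-model self-calibration, 500
  simulations for type-I error, 20 seeds for attack ordering) were
  fixed as the smallest ensembles that make the stated tolerances
  statistically meaningful.

## Interfaces

`read_otu_table()` / `write_otu_table()` speak the common OTUs-as-rows
TSV dialect with a trailing semicolon-delimited taxonomy column
(Greengenes-style prefixes tolerated); orientation is declared by a
flag, never guessed. `run_pipeline()` validates its whole configuration
before any computation, processes each kingdom independently end to
end, excludes Ambiguous samples from every stage-conditioned step, and
writes a manifest containing a configuration hash and a content hash of
all results — identical seeds yield byte-identical manifests. Thin
command-line wrappers (`inst/scripts/synth.R`, `inst/scripts/run.R`)
expose generation and the full pipeline to shell users; the R functions
remain the primary interface.
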