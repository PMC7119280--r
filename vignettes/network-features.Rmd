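---
title: "Network-based expression features: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based expression features: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfeat)
```

## The problem

Single-gene expression signatures for binary clinical outcomes (here: breast
cancer metastasis within five years of diagnosis, "poor", versus
recurrence-free survival, "good") are notoriously unstable across patient
cohorts, and with ~10,000 genes against hundreds of patients the
discriminative signal per gene is weak. A long-standing proposal is to
aggregate expression over *genesets* — a gene together with its direct
neighbors in a biological network — on the premise that proteins act in
complexes and the complex, not the gene, carries the phenotype. `netfeat`
implements the comparative-evaluation machinery needed to test that
proposal without the confounders that plague the literature (feature
selection, normalization choices, dimension reduction): fixed feature
definitions, a fixed classifier, and no supervised feature selection
anywhere.

## Networks

Two undirected simple graphs over the gene universe are supported:

* **Interaction network** (`load_edge_list`): a two-column edge list (e.g.
  from a curated protein–protein interaction database), restricted to the
  genes present in the expression matrix, self-edges dropped, duplicate and
  reversed pairs collapsed. Genes without retained interactions stay in the
  graph as degree-0 nodes, so every feature type is defined for every gene.
* **Co-expression network** (`build_mutual_knn`): gene *g* and *h* are
  joined iff each lies in the other's top-*k* most correlated genes
  (Pearson, all cohorts pooled). Mutuality caps every degree at *k* and
  yields sparse graphs whose degree distribution is heavy-tailed relative
  to the mutuality cap. "Most co-expressed" defaults to the largest
  *signed* correlation; `ranking = "absolute"` is available for users who
  regard strong negative co-expression as adjacency. Ties at the *k*-th
  rank are broken by lexicographic gene id, so construction is fully
  deterministic. `choose_k_for_edge_count` returns the smallest *k* whose
  edge count reaches a target, which is how the co-expression network is
  sized to match an interaction network (the count is nondecreasing in *k*,
  so "smallest k meeting the target" is a well-defined, reproducible
  contract; a closest-k rule would need an arbitrary tie-break).

## The fifteen feature types

For each patient independently, with `N(g)` the neighbors of gene `g` and
the geneset `{g} ∪ N(g)`:

| type | value per patient |
|------|-------------------|
| `Gene` | the gene's own expression |
| `*NO` | mean over `N(g)` only |
| `*MEAN`, `*MAX`, `*MIN`, `*MED` | that statistic over the geneset |
| `*VAR` | population variance over the geneset |
| `*Edge` | per network edge: sum of the two endpoint values |

with `*` one of `CE` (co-expression) or `PPI` (interaction), giving
1 + 2×7 = 15 types. Three conventions the definitions leave open:

* **Degree-0 `NO` fallback.** The neighbors-only average is undefined for
  an isolated gene; `netfeat` falls back to the gene's own expression.
  This keeps `NO` defined and non-constant for every gene — important
  because in sparse interaction networks a substantial fraction of genes
  are isolated, and those genes demonstrably appear among top-ranked `NO`
  features.
* **Variance convention.** Population variance (denominator = geneset
  size), so a singleton geneset has variance exactly 0 rather than `NaN`.
* **Even-sized medians** use the mean of the two central values.

Feature identifiers are stable join keys: gene ids for node-based types,
`geneA|geneB` with sorted endpoints for edges. Every feature records its
gene provenance (the geneset, or the two endpoints), which downstream
robustness analysis consumes.

## Significance screening

Each feature is scored with a two-sided pooled-variance (Student's) t-test
between the outcome groups — Student's rather than Welch's because the
evaluated protocol specifies it — and p-values are adjusted with the
Benjamini–Hochberg step-up procedure; features pass at an FDR-corrected
threshold of 0.1. Constant features receive p = 1 with a warning instead of
being dropped, so the feature universe stays identical across cohorts.
Ranking for top-feature selection uses *raw* p-values; adjusted values gate
only significance counts.

## Robustness across cohorts

For each feature type and cohort, the top-160 features by raw p-value are
selected and mapped to genes: node-based features contribute their own
gene; for edge features, ranked edges are walked in order, endpoint genes
inserted into an ordered set until it holds 160 genes, then truncated in
insertion order (one consistent reading of "pool genes of top edges until
160 are obtained"). With 160 genes from a universe of 12,750, two
independent draws share k²/N ≈ 2 genes in expectation, which is why 160 is
the canonical signature size. For each unordered cohort pair the observed
overlap is divided by k²/N (kept at full precision; the "= 2" is a rounded
presentation) and the geometric mean over all pairs — 66 pairs for 12
cohorts — summarizes the type's robustness. A zero overlap is floored at a
half-count pseudocount (configurable) before division so log-scale
summaries stay defined.

Degree diagnostics accompany every summary: the mean and median network
degree of each cohort's selected genes versus the network average. Edge
features systematically select hub genes — a hub participates in many
edges and so has many chances to appear — which inflates cross-cohort
overlap for reasons unrelated to biology. The package reproduces this hub
bias on synthetic data.

## Classification and the CNF ensemble

Every feature type is evaluated with L2-regularized logistic regression
under repeated stratified 5-fold cross-validation (10 repetitions by
default), scored by AUC — the probability a random poor-outcome patient
outranks a random good-outcome one, ties credited one half — because the
cohorts are heavily class-imbalanced. Choices the protocol leaves open,
all config-exposed:

* **Ridge penalty** with inverse strength C = 1 (glmnet lambda = 1/(n·C)):
  with features far outnumbering patients an unpenalized fit is ill-posed.
* **Within-fold z-score standardization**, training statistics only:
  variance features live on entirely different scales from expression
  levels. Leakage is excluded by construction and by test.
* **Stratified folds**: unstratified splits on small imbalanced cohorts
  can produce single-class folds, for which AUC is undefined.
* **No feature selection** of any kind, matching the evaluated protocol.

The **CNF ensemble** (combined network features) fits one logistic model
per component type — MEAN, MAX, MIN, MED on both networks, eight models —
and averages their predicted probabilities per held-out patient. Within a
repetition all components share one fold assignment; without that, the
eight probabilities for a patient would come from models trained on
different data and their average would be ill-defined. When all components
coincide (edgeless networks) CNF reduces exactly to the single model, a
tested invariant.

The sample-size experiment draws class-stratified subsamples without
replacement (class ratio preserved to the nearest patient) at percentages
90% down to 10%, several draws per level, and repeats the CV on each —
measuring how much data network-based features need before they pay off.

## The synthetic generator

`generate_study` emulates the statistical structure the analysis assumes,
not microarray physics. Genes are partitioned into modules of
`module_size`; each patient has one latent activity per module
(standard normal), shifted by ±δ/2 by class in differential modules; a
gene's value is λ × (its module's activity) + a per-cohort per-gene batch
offset (SD `batch_sd`) + independent noise (SD `noise_sd`), mean-centered
per gene afterwards. The generator ships ground truth: the true network
(a clique per module) plays the interaction-network role, and the
differential gene list supports recovery tests. `signal_mode =
"single_gene"` plants the shift on individual genes with unshifted
latents, producing the opposite regime in which aggregation cannot help.

Defaults are fixed study conditions, chosen once to represent a realistic
weak-per-gene regime: 200 genes in modules of 10, six differential modules,
δ = 1, λ = 0.4, noise SD 1, batch SD 0.3, and the 12-cohort size/imbalance
profile of the reference compendium (455 poor / 1,161 good / 1,616
patients, scalable). With λ = 0.4 a single gene's class separation is
d ≈ 0.37 — individually near-useless, while a module mean is d ≈ 0.73 —
which is precisely the mechanism by which neighborhood aggregation and the
CNF ensemble earn their advantage at large n and lose it at small n. What
the generator does *not* emulate: probe-level artifacts, heavy-tailed
noise, outcome-correlated batch structure, scale-free interaction
topology, or survival censoring; passing tests therefore demonstrate the
machinery's correctness and the claimed qualitative regimes, not clinical
performance on real cohorts.

All randomness in a run flows from one master seed through R's
Mersenne-Twister stream, seeded once per generator call; cross-validation
repetition r draws its folds with `seed + r − 1`, and subsample s at
percentage level i uses `seed + 1000·i + s`, so every result is bit
reproducible from its configuration.

## Numerical choices and problem sizes

Correlation matrices are computed densely (a 12,750-gene universe needs
~1.3 GB transiently; the k-selection search reuses one rank matrix rather
than rebuilding networks). MEAN/NO/VAR aggregation runs through a sparse
adjacency product; MAX/MIN/MED loop per geneset. Expected overlaps and
fold changes are kept at full precision. glmnet is run with a short
decreasing lambda path ending at the target for convergence stability
(threshold 1e-8, deterministic). The packaged experiments run at reduced
sizes chosen for single-workstation turnaround: the large-sample
experiments use the 12-cohort profile scaled to ~1,200 patients with one
CV repetition, the subsample experiment two draws per level, and the null
control 100 simulated studies of 2,000 genes × 300 patients. These sizes
are the package's own defaults for its shipped analyses; all counts
(repetitions, draws, seeds) are parameters.

## Known limitations

* The co-expression network is built on the pooled matrix, including any
  class signal; building it on training folds only would be stricter but
  is not what the evaluated protocol does.
* Robustness differences between feature types are summarized, not
  significance-tested; conclusions drawn from them are qualitative.
* The logistic models are not calibrated; CNF averages raw probabilities.
* Edge-feature universes grow with the edge count, and no attempt is made
  to subset edges; with very dense networks the edge models become
  expensive and their AUC can suffer from the feature-to-patient ratio.
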