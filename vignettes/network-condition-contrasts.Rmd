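---
title: "Contrasting task conditions on weighted brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting task conditions on weighted brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcontrast)
```

## The analysis

netcontrast implements a three-stage analysis of paired task conditions
(here labelled *fear* and *neutral*) measured as per-participant weighted
functional-connectivity matrices over a fixed brain parcellation:

1. **Graph metrics over a cost sweep.** Each matrix is absolute-valued
   (negative correlations are kept as connection magnitudes), proportionally
   thresholded at every cost of a grid (default 1–50% in 1% steps, weights
   preserved), and summarized per threshold by four measures: participation
   coefficient (PC) and betweenness centrality (BC) per node, global
   efficiency and Newman-spectral modularity per graph. Values are averaged
   across the grid, giving one PC/BC vector and one efficiency/modularity
   scalar per participant-condition.
2. **Mass-univariate contrasts.** Per node, a linear mixed model
   `value ~ condition + age + (1 | dataset/participant)` estimates the
   age-adjusted fear-minus-neutral contrast; Benjamini–Hochberg FDR is
   applied across nodes within each metric. Two further models contrast the
   global metrics.
3. **Multivariate classification.** A linear soft-margin SVM classifies
   fear vs neutral rows from the per-node metric vectors inside stratified,
   participant-level 4-fold nested cross-validation, repeated with
   re-drawn folds; significance comes from a permutation null (condition
   labels swapped within participants) and feature importance from
   z-scored average weights.

Because no imaging data ship with the package, a synthetic-connectome
generator provides cohorts with known ground truth; every stage is tested
against it and against enumeration oracles.

## The graph model

A thresholded matrix defines a weighted undirected graph with adjacency
$A_{ij} \ge 0$, node strength $k_i = \sum_j A_{ij}$ and total weight
$m = \tfrac12 \sum_{ij} A_{ij}$. With a community partition $c$ (for PC: the
a-priori 8-network assignment; for modularity: the data-driven Newman
division):

* $PC_i = 1 - \sum_s (k_{is}/k_i)^2$, with $k_{is}$ the strength of $i$
  into community $s$; $PC_i = 0$ for isolated nodes by convention.
  $PC_i \in [0,\, 1 - 1/M]$.
* $c_B(v) = \sum_{s<t,\, s\ne v\ne t} \sigma_{st}(v)/\sigma_{st}$ over
  unordered pairs, unnormalized, on shortest paths with edge lengths
  $L_{ij} = 1/A_{ij}$ (stronger = closer, the convention of the standard
  brain-connectivity tooling; the choice matters and is stated here because
  path-based measures are meaningless on raw correlation "lengths").
* $E_{global} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$, disconnected
  pairs contributing zero.
* $Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{k_i k_j}{2m}\right)
  \delta(c_i, c_j)$, resolution fixed at 1.

### Proportional thresholding

`prepare_adjacency(matrix, cost)` keeps the $\lceil cost \cdot N(N-1)/2
\rceil$ largest of **all possible** upper-triangle magnitudes (not of the
observed nonzero ones), zeroing the rest and mirroring. Ties at the cutoff
are broken by (row, column) lexicographic order so results are
reproducible. At cost 1 the operation is the identity up to the absolute
value. Modularity is computed on the thresholded graph at every cost, like
the other measures, and averaged across the grid exactly as the local
measures are.

### Community detection

`newman_communities()` implements spectral modularity maximization:
recursive bisection by the sign of the leading eigenvector of the
(generalized) modularity matrix, Kernighan–Lin node-swap fine-tuning after
each split, splits accepted only when they increase $Q$. The complete
division is then fine-tuned by a KL pass that moves single nodes between
arbitrary communities (including opening new ones) and greedily merges
community pairs whose union raises $Q$. The same polishing is run from the
multi-way divisions given by the sign patterns of the top 1–3 eigenvectors
(Newman's multi-eigenvector generalization) and — on graphs of ≤ 100
nodes — from an all-singletons start; the highest-$Q$ division is
returned. On all random graphs of ≤ 8 nodes we have tested, this attains
the exhaustive-partition optimum to machine precision (the test suite
checks 200 such graphs per run); on large graphs it is a strong local
optimizer with no global guarantee, like all modularity maximizers.

Determinism: eigenvectors come from a deterministic symmetric solver, each
eigenvector's sign is fixed by its largest-magnitude entry, zero entries
join the positive group, and all tie-breaks are index-ordered. KL rounds
re-evaluate their objective exactly at round end — accumulated incremental
gains carry floating-point drift that can otherwise masquerade as endless
improvement.

### Path measures

Betweenness and global efficiency are computed by one shared pass of
Brandes' algorithm (compiled; both need the same single-source shortest
paths, and the sweep calls them at every cost). Path-length ties are
detected with an absolute 1e-12 tolerance. The unit tests verify both
measures against exhaustive simple-path enumeration and against igraph.

## The mixed model

The long metric table has one row per (participant, condition, node). The
per-node model is fit by REML with random intercepts for dataset and for
participant nested in dataset. With only four dataset levels the dataset
variance is frequently estimated at zero; the fit then falls back to a
participant-only random intercept (recorded in the `fallback` column), and
in the fully degenerate case of zero residual variance (possible in
synthetic data) to the paired-design limit, ordinary least squares with
participant as a fixed factor. The contrast is the `condition` coefficient
with neutral as reference, so negative $b$ means *lower in fear*. The
t-statistic uses $df = n_{participants} - 1$; no Satterthwaite machinery is
available in this dependency set, and with paired data and one contrast
this convention matches the degrees of freedom a paired test would report.
FDR is Benjamini–Hochberg (`p.adjust`), applied across nodes within one
metric; NA p-values (unfittable nodes) pass through without affecting
ranks.

## Classification

* **Solver.** No SVM package is available in the dependency set, so the
  package carries a LIBLINEAR-style dual coordinate descent solver for the
  L1-hinge linear SVM, with the bias as an augmented regularized feature.
  Tests certify solutions via the dual KKT conditions, a closed-form
  max-margin toy, and agreement with an independent hinge-loss
  implementation. The working tolerance (max projected-gradient violation
  1e-4) is far below anything that affects predictions at these data
  scales.
* **Folds.** Assignment is by participant — both condition rows travel
  together, so no within-subject leakage is possible — and stratified by
  dataset (per-dataset counts across folds differ by at most 1). Datasets
  smaller than the fold count trigger a warning and global balancing.
* **Nested CV.** The inner loop rotates over the $k-1$ training folds to
  pick the misclassification cost $c$ from a grid (default 1–10, step 1;
  the grid's range is a package choice, its unit step is part of the
  stated protocol) by pooled inner accuracy, ties to the smallest $c$.
  Features are standardized with training-fold statistics only. Outer test
  predictions are pooled within a repetition; accuracy, macro dice and
  primal weights (standardized scale) are averaged across repetitions,
  each with freshly drawn folds.
* **Permutation null.** Condition labels are swapped within participant —
  the exchangeable unit of a paired design — with fresh folds per
  permutation. $p = \#\{null \ge true\}/n$ (count/n, matching a reported
  $p_{1000} = 0.003$; the (count+1)/(n+1) variant is a flag). Feature
  flagging is two-sided at $|z| > 1.96$ on weights z-scored across
  features; signed z values are reported.
* **Degenerate classifiers.** A constant single-class prediction on a
  balanced set forces accuracy 50% and macro dice
  $\tfrac12\!\left(\tfrac{2 \cdot 1/2}{1 + 1/2} + 0\right) = 1/3$;
  `degenerate_report()` flags such collapses and reports the forced values.

### A note on null calibration

The protocol's p-value compares an *averaged* true accuracy (over many
repetitions) against *single-run* null accuracies. Under a pure-noise null
the average concentrates at the null mean, so this p-value is **not**
uniform — it piles up near 0.5 by construction. That is a property of the
statistic, not of the implementation. Calibration tests therefore set
`n_true_reps = 1` (one true evaluation per experiment, the exchangeable
case), where count/n p-values are approximately uniform; the behaviour of
the averaged statistic is checked separately (mean null accuracy within
3 SE of 50%).

## The synthetic world

`generate_cohort()` draws, per participant and condition, a symmetric
matrix $W_{ij} = s_{ij}\,(\mu_{ij} + b_{subj} + b_{ds} +
\varepsilon_{ij})$: block means $\mu$ (within-network 0.5, between-network
0.2), subject and dataset intercepts (SD 0.05 / 0.03), edge noise (SD
0.1), and a sign $s_{ij} = -1$ on a fixed random 30% of between-network
edges — an anticorrelation structure shared across the cohort so that
negative edges are a property of the connectome, not of the draw. In the
fear condition, every edge inside the affected network (default
somatomotor) gains `effect_delta` (default 0.15). Ages are normal (mean
22.06, SD 4.79) truncated at 18; default dataset sizes are 18/29/34/28.
Raising within-network weights concentrates a node's strength in its own
community, so planted nodes' participation coefficients *fall* in the fear
condition — the direction the univariate stage is tested to recover.

What the generator does **not** emulate: BOLD time series, motion or
denoising artifacts, distance-dependent connectivity, hub structure beyond
the block model, or heavy-tailed weight distributions. A green
parameter-recovery test therefore establishes that the pipeline recovers
planted block-model effects — not that it would detect any particular
effect in real imaging data. Weights live on an unconstrained real scale
(only ranks survive absolute-value thresholding); a `clip` option bounds
them to $[-1, 1]$ where an efficiency bounded by 1 is wanted.

## Scale choices in scripts and tests

The full protocol (412 nodes, ~109 participants, 50 costs, 1,000
permutations) costs hours of CPU; scripts and tests default to desk-scale
worlds (64–120 nodes, 40 participants, coarser grids, 50–200 permutations)
and say so where they do. The analysis drivers accept `--full` /
`--permutations` to run the protocol at scale. Sample sizes follow the
listed per-dataset exclusions (18/29/34/28); the source cohort's own totals
are internally inconsistent, so the manifest keeps cohort size fully
configurable.

## Known limitations

* The dataset-level random effect is rarely estimable with 4 datasets; the
  documented fallback makes this explicit rather than hiding it.
* The contrast's df convention is a choice; with paired designs it matches
  the natural paired-test df, but other software may report different df.
* Community detection at pipeline scale is a local optimizer; modularity
  values from different implementations can differ in the third decimal.
* Accuracy of the permutation p is limited to 1/n_permutations; the
  count/n convention can return exactly 0.
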