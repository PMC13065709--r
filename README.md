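# netcontrast

Condition contrasts on weighted brain networks: an analysis pipeline for
asking whether, and where, the functional network organization of the
brain differs between two task conditions (here *fear* vs *neutral*
stimulus evaluation), using graph theory over per-participant
functional-connectivity matrices pooled across several datasets.

It is written for network-neuroscience analysts who have per-subject,
per-condition connectivity matrices (one square weighted matrix per
delimited text file) on a fixed parcellation — by default 412 nodes: 400
cortical parcels in 7 canonical intrinsic connectivity networks plus 12
subcortical regions treated as an 8th network — and want the full
inferential chain, testable end to end without any imaging data.

## The method

For each matrix, negative edges are kept as magnitudes (`|W|`) and the
strongest `cost` fraction of all possible edges is retained over a grid of
proportional thresholds (1–50%, weights preserved). At each cost the
pipeline computes, and then averages across the grid:

* participation coefficient `PC_i = 1 − Σ_s (k_is / k_i)²` on the
  a-priori network partition (low PC = strength concentrated in the node's
  own network),
* unnormalized weighted betweenness centrality
  `c_B(v) = Σ_{s<t} σ_st(v)/σ_st` on edge lengths `1/A_ij`,
* global efficiency `E = (1/(N(N−1))) Σ_{i≠j} 1/d_ij`,
* modularity `Q = (1/2m) Σ_ij (A_ij − k_i k_j/2m) δ(c_i,c_j)` of the
  division found by Newman spectral community detection with
  Kernighan–Lin fine-tuning.

Per-node condition contrasts come from linear mixed models
`value ~ condition + age + (1 | dataset/participant)` with
Benjamini–Hochberg FDR across the nodes of each metric; global metrics get
the same model. A linear SVM (stratified, participant-level 4-fold nested
cross-validation; inner loop selects the cost parameter c) classifies
fear vs neutral rows, with significance from a within-participant
label-swap permutation null and feature importance from z-scored average
weights (|z| > 1.96 flagged).

A synthetic-connectome generator (block-structured matrices with negative
between-network edges, nested subject/dataset variation, and a planted
within-network fear effect that demonstrably lowers affected nodes' PC)
provides ground truth for every stage.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a
desk-scale synthetic world (120 nodes, 40 participants in 4 datasets,
planted +0.15 somatomotor effect):

```sh
Rscript analysis/01_simulate.R --seed 7 --out results
Rscript analysis/02_metrics.R  --results results --cost-step 0.05
Rscript analysis/03_univariate.R --results results
Rscript analysis/04_classify.R --results results --permutations 50 --seed 7
```

which prints (abridged; exact output of the run above):

```
planted effect: +0.15 on within-Somatomotor edges (24 nodes)
PC: 29/120 nodes significant at FDR < 0.05 (28 negative)
  by network: Somatomotor=24, DorsalAttention=2, VentralAttention=2, Default=1
BC: 0/120 nodes significant at FDR < 0.05 (0 negative)
e_global: mean_diff = +0.0054, b = +0.0054 (SE 0.0005), t(39) = 12.07, p = 9.57e-15
q: mean_diff = -0.0191, b = -0.0191 (SE 0.0008), t(39) = -23.32, p = 1.64e-24
ground truth: 24/24 planted nodes recovered, 4/96 null nodes flagged
pc: accuracy 96.03%, dice 0.960, p_perm = 0.000, 5 feature(s) |z| > 1.96
```

Read: every one of the 24 planted somatomotor nodes shows a significantly
*lower* participation coefficient in the fear condition (intra-network
strengthening pulls a node's strength into its own community), betweenness
shows nothing, the global metrics shift with tiny standard errors, and the
multivariate classifier separates the conditions far above chance. Tables
land in `results/` (`univariate_*.csv`, `classification_*.json`,
`weights_*.csv`, `null_*.csv`). `--full` on stage 1 switches to the
412-node table and dataset sizes 18/29/34/28; stage 4's
`--permutations 1000` runs the full permutation protocol.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch — it generates a
seeded synthetic cohort, sweeps the cost grid, fits the mass-univariate
contrasts with FDR, and runs the permutation-tested SVM — and writes its
JSON summary to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

| Where | What |
| --- | --- |
| `R/node_table.R`, `R/connectivity_io.R` | parcellation table, matrix/manifest I/O and validation |
| `R/synthetic.R` | synthetic cohort generator and ground truth |
| `R/graph_metrics.R`, `src/` | thresholding, PC, BC, efficiency, Newman/KL modularity (compiled Brandes + KL) |
| `R/sweep.R` | cost-grid sweep and cross-threshold averaging |
| `R/univariate.R` | mixed-model contrasts, BH-FDR |
| `R/svm.R`, `src/linsvm.cpp` | folds, nested CV, permutation test, dice, weight flagging |
| `R/pipeline.R` | one-call orchestration (`run_pipeline`) |
| `vignettes/network-condition-contrasts.Rmd` | the methods account: model, assumptions, numerical choices, limitations |
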