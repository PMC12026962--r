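---
title: "Classifying post-anesthesia brain states on sample-similarity graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying post-anesthesia brain states on sample-similarity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anesgraph)
```

## The problem

Monitoring the depth of anesthesia requires telling apart brain states —
wakefulness (W), drowsy sleep (DS), NREM stages N2/N3, REM sleep,
unresponsive wakefulness syndrome (UWS), brain injury (BI), healthy
controls (HC), and eyes-open/closed resting conditions (EO/EC) — from
small tables of neuroimaging-derived features: activation values of three
thalamic nuclei (VPL, PUL, MD), white matter (WM), cerebrospinal fluid
(CSF) and the right VPL (rVPL). Cohorts assembled from several studies
are small (a few hundred samples) and heavily imbalanced (7 to 78 records
per class in the eight-state cohort), which defeats most conventional
classifiers.

`anesgraph` implements a transductive strategy for this regime:

1. **Merge** per-study feature tables into one cohort
   (`merge_tables()`), keeping every record and renumbering ids.
2. **Augment** minority classes with SMOTE interpolation to explicit
   per-class targets (`smote()`); class imbalance is deliberately
   retained rather than equalized, mirroring realistic cohorts.
3. **Build a sample-similarity graph** (`pairwise_edge_table()`): every
   sample is a node, every pair is scored by the Spearman rank
   correlation of their six feature values (cosine and a bounded
   Euclidean transform are available for comparison), and edges are kept
   when their weight is at or below a threshold `tau`
   (`threshold_filter()`).
4. **Classify nodes** with a message-passing neural network
   (`train_gnn()`, `predict()`), using train/test masks over one fixed
   graph.
5. **Evaluate** with a full multiclass panel (`metric_panel()`):
   accuracy, sensitivity, precision, specificity, NPV, FPR, FDR, FNR,
   F1, the generalized Matthews correlation coefficient and Cohen's
   kappa.

The structural assumption is homophily: samples from the same brain
state have similar feature-rank profiles, so a graph wired by rank
correlation concentrates same-class samples in tightly connected
neighborhoods that message passing can exploit.

## Edge weights

For two feature rows `x` and `y` (length `p = 6`), `spearman_rho()` is
defined as the Pearson correlation of within-row midranks. For tie-free
rows this equals the classical closed form

$$\rho = 1 - \frac{6\sum_n d_n^2}{p(p^2-1)},$$

with `d` the rank differences — the package treats the midrank
definition as primary because real-valued activations can tie; the
closed form is verified as a special case in the test suite (1e-12 on
tie-free rows). A row with six identical values has no defined rank
correlation; the default policy raises an error naming the sample, and
`on_constant = "zero"` assigns weight 0 instead.

`euclidean_weight()` maps distance to `1 / (1 + d)` so that all three
methods produce bounded, comparable weights with 1 meaning identity.

Thresholding is implemented exactly as stated for the source protocol:
an edge is **kept when its weight is at or below** `tau`, so `tau = 1`
keeps all edges of a correlation-weighted graph. This inclusive-below
semantics retains the weakest similarities at low `tau`; the sweep
(`threshold_sweep()`) exists precisely to expose how performance depends
on it, and `tau = 1` is the operating point.

## The classifier

Topology (four FFN blocks, three skip connections, two conv layers):

```
features -> FFN -> FFN                (preprocess, no internal skip)
         -> conv 1  (+ additive skip)
         -> conv 2  (+ additive skip)
         -> FFN -> FFN (+ skip)       (postprocess, residual pair)
         -> dense -> softmax
```

An **FFN block** is batch normalization, dropout, then a dense layer
with a nonlinearity (ELU by default). A **conv layer** aggregates
neighbor states — elementwise max by default, sum or mean optionally,
each optionally edge-weight-scaled — and combines the message with the
node's own state. The `"concat"` combination concatenates
`[self || message]` before a dense map, which under sum aggregation with
unit weights is algebraically the familiar
`sigma(A F W_neighbour + F W_self)` with the dense matrix partitioned as
`rbind(W_self, W_neighbour)`; the test suite checks this equivalence
against dense adjacency arithmetic on all small graphs to 1e-9. The
`"recurrent"` combination implements a single gated update: a candidate
`sigma(dense([self || message]))` scaled elementwise by a gate computed
with the configured recurrent activation (softplus by default). Message
passing always uses the full graph; mini-batches only choose which nodes
contribute to the loss.

Design choices worth knowing:

* **Input-block dropout is off by default** (`input_dropout = FALSE`).
  With only six input features, dropout at rate 0.3 on the raw input
  deletes a third of the measured signal on every training step; on
  separable synthetic cohorts this keeps training accuracy near 0.55
  indefinitely, whereas the same model without input-block dropout fits
  them essentially perfectly. Hidden blocks always keep the configured
  rate. Input dropout is a reasonable regularizer for wide inputs
  (hundreds of features) and can be re-enabled.
* **Batch-norm moment re-estimation.** Moments recorded during dropout
  training misstate the dropout-free evaluation distribution (the
  classic dropout/batch-norm variance shift). After every epoch the
  trainer runs one dropout-free full-graph pass that re-estimates each
  normalization layer's moments on its actual evaluation-time inputs;
  evaluation is deterministic and consistent with the recorded history.
* **Edge weights are computed but not consumed by default**
  (`use_edge_weights = FALSE`): at the `tau = 1` operating point the
  graph is complete and the adjacency-only reading of the conv layer is
  the cleaner baseline; the flag turns on weight-scaled aggregation.
* **No degree normalization of the adjacency** is applied for sum
  aggregation (mean and max need none); the conv layer follows the raw
  adjacency formulation.
* Weight init is symmetric uniform with fan-in scaling
  (`limit = sqrt(6 / fan_in)`); batch-norm starts at the identity with
  eps `1e-5` and running-moment momentum 0.9; the loss is softmax
  cross-entropy; SGD/Adam/Nadam/Adamax use standard update rules with
  the usual moment constants, only the learning rate is exposed.
* Prediction ties break toward the lower class index; max-aggregation
  ties resolve to the earliest edge in the (deterministic) edge order.

Defaults follow the tuned configuration of the source protocol: two conv
layers, hidden units `[32, 32]`, max aggregation, concat combination,
softplus recurrent activation, ELU, dropout 0.3, SGD with learning rate
0.01, batch size 64, 400 epochs. Where the protocol's records conflict
(its ablation prefers `[64, 64]` hidden units and the gated combination;
its final configuration table lists `[32, 32]` and concat), the final
configuration table wins for defaults and the alternatives remain
reachable through `gnn_config()`.

## Synthetic cohorts

`anesthesia_cohort()` and `extended_cohort()` generate seeded cohorts
with exactly the study compositions: eight states with 78/23/54/55/7/
37/15/21 records (290 samples), and fourteen sub-datasets over ten
states totalling 872 samples. Features are Gaussian with unit
covariance; class means sit on fixed signed binary-code unit directions
scaled by `separation`, so each class has a distinct feature-rank
profile. `separation` rescales the spread of class means about their
centroid: 0 collapses all classes onto one distribution, and values of
5 or more give clearly separable classes with strong Spearman homophily
(verified as a property test: within-class minus between-class mean
similarity is ~0 at separation 0 and large at 5).

What the generator does **not** emulate: the marginal distributions,
inter-feature covariance and co-activation physics of real fMRI-derived
activations, inter-study batch effects, or any physiologic relation
between states. Passing tests on synthetic cohorts therefore demonstrate
that the machinery is correct (counts, convexity, determinism, learning
capacity, invariances) — not that real cohorts reach any particular
accuracy.

SMOTE is implemented from its original definition: a synthetic point is
`x + u (x_nn - x)` with `u ~ U[0, 1]`, `x` a uniformly chosen in-class
original and `x_nn` one of its `k = 5` within-class nearest neighbors
under Euclidean distance on raw features (no standardization precedes
augmentation). `k` is truncated to `m - 1` for classes with `m <= k`
originals, and a singleton class falls back to exact duplication since
interpolation is undefined there. Per-class targets are explicit
configuration — the study's printed post-augmentation counts are
intentionally unbalanced, so no balance-to-majority rule is applied.

## Splits, standardization, evaluation

The train/test protocol of the source study is unrecorded; the package
uses a stratified 80/20 random split (`assemble_graph()`), guaranteeing
every class with at least two members a test and a train node; singleton
classes go to training with a warning. Features are z-scored with
training-node statistics only (zero-variance columns keep scale 1).

All rate metrics are **macro-averaged one-vs-rest** values over the
classes present in the true labels: the panel reports single numbers for
an imbalanced multiclass task, and macro averaging weighs every class
equally, consistent with the emphasis on minority states.
Micro-averaging would produce different numbers. Per-class 0/0 ratios
contribute 0 with a warning. MCC uses the generalized matrix-correlation
form (reducing to the binary formula for two classes); kappa is
`(p_o - p_e) / (1 - p_e)`.

## Experiments

`run_pipeline()` drives the full chain from one declarative config and
writes the sample table, edge table, training history, metrics report
and a provenance log (component seeds, counts, config hash); identical
configs reproduce artifacts bit-identically, and one master seed expands
deterministically into the simulation, oversampling, split and training
seeds.

`greedy_ablation()` sweeps the eight hyperparameter axes sequentially in
plan order, freezing each axis's best candidate (highest test accuracy,
ties to the first listed) before the next axis — a greedy protocol, not
a grid. Selecting on test accuracy mirrors the source protocol and is
optimistically biased; pass a config whose split you treat as validation
if the bias matters. `threshold_sweep()`, `compare_edge_methods()` and
`compare_oversampling()` hold every seed fixed across their arms.

## Problem sizes used in tests

Unit tests run on cohorts of 6–290 samples. The learning-sanity check
and the acceptance script train 30 epochs on the full augmented cohort
(1197 nodes, 714,610-edge class of complete graphs at `tau = 1` uses
1196 samples for the edge-count law): on the separation-5 synthetic
cohort the model crosses 0.95 training accuracy within roughly ten
epochs, so 30 epochs leave comfortable margin while keeping the run to
a few minutes; the 400-epoch default remains for real experiments.

## Limitations

* Pair enumeration is exact and quadratic; cohorts beyond a few
  thousand samples need sparsification that the package deliberately
  does not provide.
* The classifier is transductive: adding samples means rebuilding the
  graph and retraining; there is no inductive inference path.
* Training is single-threaded and deterministic by construction;
  identical results across machines assume identical floating-point
  behavior.
* The source study's headline accuracies depend on its external data
  and unrecorded split; nothing in this package asserts them, and the
  synthetic cohorts are not a substitute for validating on real data.
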