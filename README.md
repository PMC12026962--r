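# anesgraph

Classification of post-anesthesia brain states from small, imbalanced
tables of neuroimaging-derived features, for researchers working on
anesthesia-depth monitoring and consciousness-state discrimination.
Cohorts in this area merge a handful of public studies into a few
hundred samples spread very unevenly over states — wakefulness (W),
drowsy sleep (DS), NREM stages N2/N3, REM sleep, unresponsive
wakefulness syndrome (UWS), brain injury (BI), healthy controls (HC)
and eyes-open/closed conditions (EO/EC) — each described by six
activation features: the VPL, PUL and MD thalamic nuclei, white matter,
CSF and the right VPL.

`anesgraph` turns such a table into a transductive node-classification
problem:

1. **Merge** per-study sub-tables into one cohort, keeping all records.
2. **Oversample** minority classes to explicit per-class targets with
   SMOTE: each synthetic record is `x + u (x_nn − x)`, `u ~ U[0,1]`,
   interpolating between an original and one of its k = 5 within-class
   nearest neighbors (random duplication is available for comparison).
3. **Build a sample-similarity graph**: nodes are samples, and every
   pair (i, j) is weighted by the Spearman rank correlation of their
   feature rows — for tie-free rows
   `rho = 1 − 6 Σ d² / (p(p² − 1))`, p = 6 — with cosine similarity and
   `1/(1 + d_euclid)` as alternatives; edges with weight ≤ τ are kept.
4. **Classify nodes** with a message-passing network built from FFN
   blocks (batch norm → dropout → dense) joined by skip connections
   around two conv layers, each computing
   `σ(A F W_neighbour + F W_self)`-style updates with max / sum / mean
   neighbor aggregation.
5. **Evaluate** with the full multiclass panel: accuracy, sensitivity,
   precision, specificity, NPV, FPR, FDR, FNR, F1, generalized MCC and
   Cohen's kappa, all rates macro-averaged one-vs-rest.

A seeded synthetic-cohort generator reproduces the study compositions
(eight states, 78/23/54/55/7/37/15/21 records = 290 samples, SMOTE
targets summing to 1197; a ten-state extension of 872 samples across 14
sub-datasets) so the entire pipeline is testable without any download.
Experiment runners cover the greedy hyperparameter ablation, the edge
threshold sweep, and oversampling / edge-weighting comparisons, all
seed-reproducible with provenance logs.

## Worked example

```r
library(anesgraph)

cohort <- anesthesia_cohort(seed = 1, separation = 5)   # 290 samples
class_counts(cohort)
#>   W  DS  EO  EC  N3 UWS REM  N2  BI  HC
#>  78  23   0   0  54  55   7  37  15  21

aug <- smote(cohort, oversample_spec(smote_targets(), seed = 2))
nrow(aug)
#> [1] 1197

edges <- threshold_filter(pairwise_edge_table(aug, "spearman"), tau = 1.0)
nrow(edges)          # complete graph on 1197 nodes
#> [1] 715806

graph <- assemble_graph(aug, edges, train_fraction = 0.8, split_seed = 3)
fit <- train_gnn(graph,
                 gnn_config(num_classes = nlevels(graph$labels)),
                 train_config(epochs = 30, seed = 7))
pred <- predict(fit$state, graph)
report <- metric_panel(confusion_matrix(
  as.character(graph$labels[graph$test_mask]),
  as.character(pred[graph$test_mask]),
  label_order = levels(graph$labels)))
report
#> Multiclass evaluation panel (macro one-vs-rest averages)
#>    accuracy sensitivity   precision specificity         npv         fpr
#>      0.9832      0.9832      0.9821      0.9976      0.9976      0.0024
#>         fdr         fnr          f1         mcc       kappa
#>      0.0179      0.0168      0.9824      0.9808      0.9807
```

The accuracy of 0.9832 says the model labels 98% of held-out nodes of
this strongly separated synthetic cohort correctly; specificity/NPV near
1 and FPR near 0 reflect that one-vs-rest negatives dominate each class;
MCC and kappa near 1 confirm the agreement is far above chance. On real
cohorts the numbers depend on the data; the synthetic cohort only
demonstrates the machinery.

Experiment runners operate on one declarative config:

```r
base <- run_config(data = "study", oversample = "smote", seed = 1,
                   train = list(epochs = 30))
threshold_sweep(base, c(0.7, 0.9, 1.0))   # tau, edge count, accuracy
compare_edge_methods(base)                # spearman vs cosine vs euclidean
compare_oversampling(base)                # none vs random vs smote
greedy_ablation(ablation_plan(), base)    # 8-axis sequential sweep
```

A thin CLI wraps the same functions
(`inst/exec/anesgraph simulate|run|ablate|sweep-threshold|compare-edges|compare-oversampling|metrics`),
with YAML run configs via `read_run_config()`.

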