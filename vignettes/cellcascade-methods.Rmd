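---
title: "Hierarchical cell-type annotation with cellcascade: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical cell-type annotation with cellcascade: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-cell RNA-seq atlases of developing tissues carry *multilayered*
identities: a cell is first a cardiomyocyte rather than an endothelial or
mesenchymal cell, then an atrial versus ventricular cardiomyocyte, then —
within ventricular cells — a left-ventricular, right-ventricular or septal
subtype, and some of those subtypes only exist at particular developmental
stages. Flat classifiers trained on the union of all labels mix these
resolutions and degrade precisely where the interesting biology lives, in
the closely related subtypes. `cellcascade` instead mirrors the annotation
hierarchy itself: one multiclass gradient-boosted tree classifier per layer
node, trained only on the cells of that node's branch, with query cells
cascaded down the tree and stopped wherever the model's confidence falls
below a rejection threshold.

## The model

**Inputs.** A cells × genes expression matrix of log-normalized values, a
metadata table with one column of labels per annotation layer (blank = the
cell is not in that branch), and a hierarchy file in which each CSV row is
one root-to-leaf label path. A level value prefixed `T:` marks a
developmental-timepoint partition: the layer below it is trained and
predicted separately per timepoint, so stage-restricted subtypes can never
be assigned to cells of another stage.

**Normalization.** Counts-per-10k with a natural log:
`value = ln(1 + 10^4 * count / total)`. The pseudocount of one is our
resolution of the log-of-zero problem; it preserves sparsity (zeros map to
zero) and within-cell rank order. `normalize_counts()` refuses cells with
zero totals rather than guessing.

**Per-layer classifiers.** Each layer node gets an XGBoost multiclass model
(`multi:softprob`) trained on the *full* gene list — no feature
pre-selection — using only cells whose metadata matches the node's
parent-label path (and timepoint, where partitioned). Class labels are
encoded in lexicographic order so models are portable across platforms and
runs. A node left with a single class after subsetting becomes a constant
predictor emitting probability 1; classes with no surviving cells are
dropped from the label coding with a warning.

**Hyperparameters.** A randomized search (default 50 trials) is run once at
the topmost layer and the winning configuration reused for all layers
(`tune_policy = "root_only"`; per-layer re-tuning is available). Search
ranges: learning rate log-uniform in [0.01, 0.3], maximum depth uniform in
{3..10}, per-tree row subsampling in [0.5, 1], per-tree feature subsampling
in [0.3, 1]; 200 boosting rounds with early stopping (patience 20). Trials
are scored on a stratified 80/20 validation split by misclassification
rate; a literal mean-absolute-error-on-encoded-labels criterion is
available via `loss = "mae"`, but since MAE over arbitrary integer codes of
nominal classes depends on the label ordering we surface it as an explicit
option rather than a default.

Early stopping monitors the multiclass log-loss, not the error rate. This
is a deliberate numerical choice: on cleanly separable layers the
validation error rate reaches zero at the very first round, and stopping on
it freezes boosting there, leaving class probabilities uninformatively
close to uniform. Log-loss keeps improving as margins grow, so the stored
models emit confident, well-separated probabilities — which matters because
the rejection option thresholds exactly those probabilities.

**Rejection option.** At every layer a cell is assigned its argmax class
only when the maximum class probability reaches the threshold (default
0.5, user-adjustable, optionally per layer); otherwise it is reported
`"Unclassified"` and not routed deeper. The output therefore distinguishes
three states per layer: assigned, `Unclassified` (evaluated, rejected), and
not evaluated (the cascade never reached that layer for this cell).
Probability ties at the argmax break lexicographically, for determinism.

**Missing genes.** Queries from other platforms or species rarely cover the
training gene space. `align_genes()` reorders query columns to the trained
feature list and marks absent genes as *unobserved* rather than imputing
zeros: a zero asserts "not expressed", absence asserts "not measured".
Unobserved genes are materialized as missing values, which the tree
ensemble routes through the default branches it learned during training.
Cross-species prediction first renames genes through a user-supplied
two-column ortholog table (`map_orthologs()`, many-to-one collisions
resolved by mean/max/first) — file-driven by design, never a network call,
so runs are reproducible offline.

**Marker ranking.** `attribute_layer()` computes exact tree-path Shapley
values (TreeSHAP, via the booster's native contribution predictions) on the
margin scale, where the efficiency identity — contributions plus base value
equal the model margin — holds exactly; the test suite verifies it against
a brute-force Shapley enumeration on a small ensemble. Per-class gene
scores are the sum of attributions over the sampled cells (default a seeded
subsample of at most 2000), and `rank_features()` reports the top positive
and top negative predictors per class. One adjustment to raw TreeSHAP: the
contributions of genes the sample never measured are folded into the base
value, so an unmeasured gene scores exactly zero and cannot enter marker
rankings on the strength of its default-path routing. A mean-per-cell score
is available for comparisons across samples of different size. For layers
below the root, rankings should be computed on that layer's own branch
cells (the CLI does this automatically when metadata is supplied):
summed over out-of-branch cells, the dominant positive evidence for a
class is the *absence* of its sibling's markers, which buries the class's
own markers in the list.

## Evaluation design

`holdout_split()` makes per-class stratified splits (held-out share within
one cell of the target per class; the default mirrors the conventional
90/10 design). `cross_validate()` runs independent reshuffles of the
supplied partition — each fold re-splits 90/10 with stratification on the
cells' full label paths, retrains every layer, and scores every layer on
its true-branch cells, pooling timepoint-partitioned nodes of a layer.
Aggregates are reported as mean ± half-width of a normal-approximation 95%
confidence interval over folds. `compute_metrics()` excludes rejected
(`Unclassified`) cells from the accuracy/precision/recall/F1 denominators
and reports them as a separate rate; headline precision/recall/F1 are macro
averages over true classes, with micro values also emitted.
`confusion_matrix()` reports counts and row-normalized percentages, with an
optional `Unclassified` column under which every routed cell appears in
exactly one matrix cell.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws negative-binomial counts (dispersion is the NB
`size`; smaller = noisier) with per-cell library sizes uniform over a
range, against a known hierarchy in which every class of every layer node
owns a disjoint block of marker genes elevated by `exp(marker_log_fold)`.
Cells of a terminal class carry the elevated markers of *every* node class
along their path, producing the nested signal that hierarchical
classification exploits; timepoints come from the leaf's `T:` level.
`make_ambiguous_cells()` emits noise-free cells whose expression is the
coordinatewise mean of two classes' generative profiles — exactly
equidistant from both centroids — used to probe the rejection option.

The default conditions (`default_synthetic_spec()`) are a 2 → 4 → 8 class
hierarchy, 200 cells per terminal class, 500 genes, 20 markers per class at
natural-log fold 1.5, NB dispersion 2 and library sizes 2000–5000: strongly
separable, as befits a fixture whose contract is that a correct
implementation achieves ≥95% held-out accuracy at every layer. What the
generator deliberately omits: batch effects, ambient RNA, doublets,
cell-cycle structure, continuous differentiation trajectories, and
correlated marker programs. Passing on these fixtures therefore
demonstrates that the machinery (routing, training, rejection, attribution,
serialization) is correct — not that any particular real tissue will be
classified with these accuracies.

Two smaller designs are used where full size adds nothing: module tests run
a 2 → 4 fixture at 50 cells per terminal class, and the sample-size
experiment uses a flat 8-class task (300 genes, 5 markers per class at
log-fold 0.7, dispersion 1, library sizes 1000–3000) — hard enough that
accuracy still climbs across 16…512 cells per class instead of saturating,
with accuracy measured on an independently generated test set of 50 cells
per class.

## Numerical and design choices

- **Determinism.** Single-threaded boosting, explicit seeds everywhere
  (per-layer seeds derived arithmetically from one master seed), label
  codes in lexicographic order, lexicographic argmax tie-breaks, and
  breadth-first node ordering with lexicographic tie-breaks. Two runs with
  the same seed produce bit-identical predictions, as do bundles
  round-tripped through `save_bundle()`/`load_bundle()`.
- **Bundle format.** One JSON manifest (hierarchy paths, per-layer feature
  lists, label codes, hyperparameters, training seed, default threshold)
  plus one model artifact per layer, so a single layer object can be loaded
  and used standalone by name.
- **Degenerate inputs.** Zero-total cells, single-cell classes in splits,
  empty hierarchies, duplicate paths, labels under two parents in one layer
  context, the reserved `Unclassified` label in training data, zero gene
  overlap at alignment: all are hard, named errors. Low (but nonzero) gene
  overlap and dropped classes warn instead.
- **Timepoint routing** is metadata-driven: the query supplies per-cell
  timepoints and partitioned branches are skipped (with a warning) when it
  does not. We chose not to train a timepoint classifier as a fallback —
  stage is an experimental covariate the user knows, and silently
  predicting it would blur a routing guarantee this package makes hard:
  no cell is ever labeled by a node of another stage.
- **Blank labels** in metadata mean "not in this branch" and exclude the
  cell from that node's training set; a blank at the root layer is treated
  as a validation error, since such a cell can train nothing.

## Problem sizes

The shipped tests train the default 1600-cell fixture once with the full
50-trial search (a few minutes on one core) and reuse it across the
acceptance properties; the sample-size experiment trains 6 sizes × 4
replicates of the flat task. `scripts/acceptance.R` re-runs the same
computations from scratch at the same sizes (2 replicates for the learning
curve) and writes every reported quantity as JSON.

## Known limitations

- The cascade's errors compound: a cell misrouted at layer 1 can only be
  wrong (or unevaluated) below; per-layer evaluation on true-branch cells
  is therefore reported separately from cascaded output.
- Shapley sums over all sampled cells can be dominated by large classes;
  on balanced two-class nodes the positive evidence of one class is the
  near-mirror of the other's negative. The mean-per-cell option and
  caller-chosen attribution samples are the provided levers.
- Probabilities are raw softmax outputs; no calibration is applied, so the
  rejection threshold is a rank statistic of model confidence, not a
  calibrated error probability.
- DAG (multi-parent) hierarchies and soft labels are out of scope; the
  hierarchy is a rooted tree with at most one timepoint level per path.
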