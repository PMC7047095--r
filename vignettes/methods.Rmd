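---
title: "Methods: metadata augmentation for sRNA expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metadata augmentation for sRNA expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Public small RNA sequencing (sRNA-seq) samples frequently lack structured
metadata — tissue of origin, donor sex and age are missing or free-text.
Because samples with similar sRNA expression tend to share these
annotations, the missing fields can be *augmented*: predicted from the
expression profile by a classifier trained on well-annotated samples.
`srnaugment` implements that analysis end to end — preprocessing, a dense
neural network and a two-stage random forest, two validation schemes, and
DeepLIFT-based explanation of the network — together with a synthetic
cohort generator so the whole pipeline is testable without access to any
external database.

# Preprocessing

The fixed order is **RPM → zero filter → feature-block selection → MinMax**:

* **RPM** (reads per million): every sample column is scaled to a total of
  10^6. This also cancels any uniform multiplicative per-sample effect
  (library size, a global batch scaling).
* **Zero filter**: features whose fraction of exactly-zero entries exceeds
  30% are removed. The bound is strict: a feature with exactly 30% zeros is
  retained. RPM rescales within columns only, so it neither creates nor
  destroys zeros and the filter commutes with it (this is asserted in the
  tests).
* **Feature blocks**: features are tagged `srna` or `contaminant`
  (viral/bacterial transcripts detected in the library). Tissue models
  conventionally use sRNAs only; sex and age models may use either block
  or both — `prepare_features(..., feature_set=)` selects it.
* **MinMax**: per feature, the observed range is mapped affinely to [0,1];
  constant features map to 0. *Where* the scaler is fitted is a
  leakage decision: the faithful variant fits on the full matrix before
  splitting; the package default fits on each training split only and
  clips the held-out side to [0,1]. Both are available
  (`scaler_scope = "global"` / `"train"` in `run_model_validation()`, the
  `--paper-faithful` CLI switch); the default avoids information leaking
  from test to train, and for these data the difference is negligible
  because per-feature ranges are stable across splits.

Tissue labels are merged into ontology groups through a flat
tissue→group table shipped with the package (derived from the BRENDA
tissue ontology; e.g. *blood plasma* → `blood_group`, *motor cortex* →
`brain_group`). Unknown labels pass through with a warning rather than
failing, so novel tissues remain visible.

Age is binned into 2, 3 or 4 classes with edges
`[0;65](65;110]`, `[0;45](45;70](70;110]`, `[0;30](30;60](60;80](80;110]`.
The first interval is closed at both ends and the rest are left-open
right-closed, read literally from the bracket notation: age 65 falls in
the first bin, 66 in the second.

Classes with fewer than a minimum number of samples (presets 9 or 15) are
removed before modelling; at least two classes must survive — the
degenerate one-class problem is refused rather than silently returned
(the alternative reading, returning whatever survives, makes every
downstream contract vacuous).

# The dense network

A fully connected net: hidden layers of 1000, 250 and 250 ReLU units with
dropout 0.5/0.4/0.4, a softmax output over the classes, cross-entropy
loss (the binary form for two classes; both forms share the softmax
gradient), Adam with its canonical defaults (step 0.001, β₁ 0.9, β₂
0.999, ε 1e-8), 50 epochs, batch size 30, no early stopping and no
validation split. Weights start from the Glorot scaled-uniform scheme.
The net is implemented directly on base matrix algebra rather than
through a deep-learning framework: at this scale (≤ a few thousand
inputs) BLAS matrix products are fast enough, training is bit-reproducible
under a single seed (batch order and dropout masks included), and —
decisively — every layer's pre-activations are exposed, which the
attribution code requires.

One ambiguity: "ReLU activates the input layer" could be read as applying
ReLU to the raw inputs. Inputs are MinMax-scaled to [0,1], where ReLU is
the identity, so the package applies ReLU from the first hidden layer on;
the choice has no numerical consequence for in-range inputs.

Ties in the argmax prediction break to the lowest class index, so
predictions are deterministic even for degenerate (e.g. zero-weight)
models.

# The two-stage random forest

Stage 1 grows 100 trees on all features and ranks features by Gini
importance (mean decrease in Gini impurity accumulated over trees,
weighted by node size). The top 1000 (ties broken by feature order; all
features when p < 1000) enter stage 2, a 500-tree forest. `mtry` is
⌊√p⌋ at both stages. Because forests are sensitive to class imbalance,
every class is downsampled without replacement to the smallest class size
before each stage; the two stages draw their downsamples independently so
each stage uses as much data as a balanced design allows. Whether the
original analysis balanced at one stage or both is unstated; balancing
both is the conservative reading.

No forest learner ships with this runtime, so the CART ensemble itself is
implemented in C++ (`src/forest.cpp`): Gini splits over per-node random
feature subsets, bootstrap resampling per tree, majority vote with
vote-fraction output. Bootstrap indices and per-tree RNG seeds are drawn
from R's seeded stream, making fits reproducible bit for bit.

# Validation

* **Stratified fivefold CV**: each class is shuffled and dealt round-robin
  to folds, so per-class counts differ by at most one across folds.
  Whether the original CV was stratified is unstated ("randomly selected
  a priori"); stratified is the default because it keeps small classes
  testable in every fold.
* **One-dataset-out**: one split per *eligible* dataset — a dataset
  qualifies only if every class it contains also occurs in some other
  dataset, so held-out classes stay represented in training. This is the
  batch-effect stress test: a whole study, with its library-preparation
  bias, is unseen during training.
* **Metrics**: exact confusion matrix, accuracy, per-class precision.
  Precision of a never-predicted class is reported as missing rather than
  zero, so macro averages are not silently deflated. The headline number
  across splits is the unweighted mean of per-split accuracies (one value
  per fold or held-out dataset); a size-weighted mean is also returned.

# DeepLIFT explanation

Attribution scores `C[i,j,k]` (sample × input × class) are computed with
the Rescale rule against a reference input of all zeros: multipliers are
backpropagated from the **pre-softmax** outputs — linear layers propagate
through the transposed weights, ReLU units use
Δactivation/Δpre-activation when |Δpre| > 1e-7 and the ReLU subgradient
at the reference otherwise. Targeting the pre-softmax layer makes the
conservation property ("summation-to-delta": scores for a class sum to
that output's difference from its reference value) exact for a
piecewise-linear net; softmax-level attribution is not defined by the
Rescale rule. RevealCancel is out of scope.

Derived analyses:

* **D1** class-average scores: for each feature and class, the mean over
  the class's samples of the own-class score minus the average score over
  the other classes. Top-N (default 300) features per class are the
  D1-ranked marker lists, and their per-class mean scaled expression is
  exported for heatmap rendering.
* **D2** pairwise differences for a sample of class k against a rival k′:
  `C[i,j,k] − C[i,j,k′]`, sorted descending.
* **Ablation until flip**: features are zeroed one at a time in decreasing
  D2 order (zero *is* the reference value, so ablation moves the sample
  toward neutrality); after each step a fresh forward pass is run. The
  similarity count stops when the prediction becomes k′, the stability
  count when it leaves k. Only features with strictly positive D2 are
  zeroed — beyond them, removing features that argue *against* k cannot
  be motivated by the procedure — and runs that never flip within that
  prefix are censored and excluded from means (with counts reported).
  The ordering is computed once from the initial attribution, not
  re-derived after each zeroing, matching the order-then-zero procedure.
  Only correctly predicted samples enter the averages: the procedure's
  premise is that the model currently predicts the sample's true class.
  The per-class stability value is the mean over samples of the minimum
  step count across rival orderings; whether the original analysis used
  min-over-rivals or a single ordering is unstated, and the choice is
  recorded in the report object (`stability_rule`).

# The synthetic cohort generator

`generate_cohort()` emulates the structure that makes this analysis hard:

* counts are negative-binomial (dispersion 0.3 by default — typical
  biological overdispersion for bulk RNA-seq; no distribution is stated in
  the source analysis, NB is the community standard), around log-normal
  baseline abundances, scaled to a per-sample library size drawn uniformly
  from 0.5–2 million;
* each class plants `markers_per_class` (20) disjoint sRNA markers at
  `marker_log2fc` (3) — strong, tissue-like signal;
* each dataset (study) applies one multiplicative log-normal shift to all
  its features (`batch_sd` 0.2) — the batch effect that makes
  one-dataset-out harder than CV;
* sex (log2FC 1 in males) and age (2% per year on the log scale) effects
  are planted in *both* the sRNA and contaminant blocks, so the
  six-model sex/age comparisons are distinguishable on synthetic data;
* every entry is independently zeroed with probability `zero_inflation`
  (0.1), giving the >30%-zeros filter real work.

All randomness flows from one seed; identical configurations are
bit-identical. What the generator does **not** emulate: real sRNA
sequence identity (ids are synthetic tokens), correlated co-expression
modules, compositional coupling beyond the library-size constraint,
tissue-specific dropout structure, or datasets containing multiple
tissues. A green test on this cohort therefore establishes that the
*procedures* are correct and that planted signal of the stated size is
recovered — not that any particular accuracy would be reached on real
compendia.

Two calibration notes, decided once and kept:

* Default `zero_inflation = 0.1` keeps planted markers below the 30%-zero
  threshold so marker-recovery criteria exercise the full pipeline; the
  filter-stress property is tested at an explicit 0.4.
* The nearest-centroid learnability guarantee (log2FC ≥ 2, batch SD ≤ 0.2
  ⇒ >90% CV accuracy) is instantiated without zero inflation: a Euclidean
  centroid oracle is dominated by log1p(0) dropout outliers (with 10%
  dropout it falls to ~0.75 even on markers alone), which says something
  about the oracle, not the cohort — the DL/RF ≥ 0.90 criterion
  establishes learnability of the default, dropout-afflicted world.

# Numerical choices and degenerate inputs

* RPM requires positive column sums; an all-zero sample is an error naming
  the sample.
* Constant features MinMax-scale to 0; unseen values clip to [0,1].
* `ε = 1e-7` separates the Rescale division from the subgradient branch.
* Non-finite training loss aborts with a diagnostic rather than returning
  a broken model.
* An empty zero-filter result is allowed (with a warning) — downstream
  code fails fast on the empty matrix rather than here.
* Argmax ties (prediction and vote): lowest class index. Ranking ties
  (D1, D2, importance): original feature order.

# Limitations

* The forest is a faithful but minimal CART ensemble: no surrogate splits,
  no missing-value handling, gini-only criterion.
* Attribution applies to the dense network only; the forest exposes its
  stage-1 importance vector instead.
* Hierarchical (ontology-aware) classification, miRNA enrichment against
  annotation databases, and t-SNE embeddings are out of scope.
* Reported SEA-scale accuracies (tissue ~96–98%, sex ~77%, age 77/63.5%,
  one-dataset-out ~83% vs ~81%) depend on external data and are not
  reproduced here; the acceptance suite checks properties, not those
  numbers.
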