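---
title: "Federated multi-label learning with Binary Relevance and REPTree: models and methods"
author: "fmll authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated multi-label learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmll)
```

## The problem and the model

Multi-label classification assigns each instance a *set* of labels: a survey
site may host several amphibian species at once; a frog call is annotated
with family, genus and species; a shelter record carries both a breed and a
pet category. Formally, a training set $D = \{(x_i, Y_i)\}_{i=1}^N$ pairs a
$K$-place feature vector with a label subset $Y_i \subseteq L =
\{y_1, \dots, y_q\}$, and the goal is a global model $G$ with
$G(x) \to \hat Y$.

`fmll` implements the Binary Relevance (BR) route through this problem,
embedded in a simulated federated protocol:

1. **Decomposition.** BR turns $D$ into $q$ single-target sets
   $D_{y_j}$: the $j$-th target of row $i$ is $1$ iff $y_j \in Y_i$. Each
   set keeps all $N$ rows and the full feature schema, so every client holds
   an equally sized task — the vertical-federation setting where clients
   share the sample space and differ only in the target column they own.
   Labels with more than two classes are handled by one multi-class task per
   label (`per_label` mode): the report tables this package mirrors carry
   one metric row per label (e.g. family/genus/species), not one per class,
   and a per-label tree is the decomposition consistent with that. The
   strictly binary protocol remains available (`strict_binary`) and is the
   default whenever every label is binary.
2. **Local learning.** Client $j$ fits a reduced-error pruning tree
   $M_j$ on $D_{y_j}$ (below). Clients share no state; training is
   order-independent, and the only payload that crosses the client–server
   boundary is the fitted model — never raw rows. The package enforces this
   as an interface contract (tested structurally), not as networking:
   transport, encryption and differential privacy are out of scope.
3. **Aggregation.** The server's global model is the pure union
   $G = \bigcup_j M_j$, keyed and ordered by the dataset's label order.
   Prediction concatenates the per-label outputs; for binary labels
   $\hat Y$ contains $y_j$ iff $M_j$ outputs the positive class. Nothing is
   averaged or re-weighted — BR federation is a single round of union, not
   FedAvg.

BR ignores label correlations by construction; that is a known limitation
of the transformation (classifier chains would address it) and is
inherited here deliberately, since the independence of clients is exactly
what makes the federation trivial and private.

## The REPTree base learner

The tree is grown greedily and then pruned against an internal hold-out:

* **Splitting.** At each node the learner scores every input feature:
  numeric features by the information gain (Shannon entropy, bits) of the
  best midpoint threshold between consecutive distinct sorted values;
  nominal features by the multiway split over all declared categories. A
  split is admissible only when every child would carry at least `min_num`
  instances, and only strictly positive gains are accepted. Growth stops on
  purity, on the depth cap, when no admissible split has positive gain, or
  when a node holds fewer than `2 * min_num` rows.
* **Pruning.** With pruning on, the rows are shuffled by `seed` and dealt
  into `num_folds` parts; fold 0 (one `num_folds`-th of the data) is held
  out and the rest grow the tree. Bottom-up, a subtree is replaced by its
  training-majority leaf whenever the subtree's misclassification count on
  its routed hold-out rows is no smaller than the leaf's — ties prune,
  preferring the smaller tree. The hold-out class counts are recorded on
  every surviving node (count backfitting), which is what the bracketed
  numbers in rendered trees report.
* **Missing values** route to the child that carried the greatest training
  weight, at training and prediction time alike. This is deterministic and
  simple; it is a documented divergence from implementations that use
  fractional instance weighting, and one reason bit-compatibility with any
  particular REPTree implementation is a non-goal.
* **Ordinal features** are offered to the splitter as their declared
  category rank (a numeric split candidate that respects the order);
  `ordinal_as_nominal = TRUE` treats them multiway instead.
* **Class probabilities** come from leaf class counts with `initial_count`
  additive smoothing (`spread_initial_count` divides the smoothing mass
  over the classes instead of adding it per class); an empty leaf inherits
  its nearest non-empty ancestor's distribution. These scores feed the ROC
  and PRC areas; no separate calibration is attempted.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `max_depth` | `-1` | depth cap; `-1` = unlimited |
| `min_num` | `2.0` | minimum instance weight per admissible child |
| `min_variance_prop` | `0.001` | numeric-target split threshold; carried for configuration fidelity, inert here because every target is categorical |
| `no_pruning` | `FALSE` | grow on all rows, skip pruning |
| `num_folds` | `3` | internal folds; fold 0 is the pruning hold-out |
| `seed` | `1` | seed of the internal shuffle |
| `initial_count` | `0.0` | additive smoothing of leaf distributions |
| `spread_initial_count` | `FALSE` | spread the smoothing mass over classes |
| `num_decimal_places` | `2` | rendering precision |

The defaults are the standard REPTree configuration. Batch-size and
debug-style keys are accepted in configurations and ignored with a notice:
they cannot affect the learned model.

### Rendering

`render_tree()` prints one line per branch or leaf; a leaf reads
`CLASS (a/b) [c/d]` with `a` the training instances reaching the leaf and
`b` those misclassified. The bracket has two readings in circulation:
majority/minority hold-out counts at the leaf (the default here,
`bracket = "majority_minority"`) and hold-out total/misclassified
(`bracket = "holdout_error"`, the conventional Weka reading). Both are
exposed because the two conventions are genuinely ambiguous in published
tree figures; no further intent is guessed.

## Evaluation stack

* **Per-label metrics.** For binary labels the standard confusion-matrix
  rates with the label's designated positive class:
  $ACC=\frac{TP+TN}{TP+TN+FP+FN}$, $PR=\frac{TP}{TP+FP}$,
  $TPR=\frac{TP}{TP+FN}$, $FS=\frac{2TP}{2TP+FP+FN}$,
  $TNR=\frac{TN}{TN+FP}$, $FPR=\frac{FP}{FP+TN}$. A zero denominator yields
  0 with a warning, keeping every report total. Multi-class labels use
  prevalence-weighted one-vs-rest averaging of the same rates.
* **Curve areas.** The ROC area is computed in its rank (Mann–Whitney)
  form, $P(s_+ > s_-) + \tfrac12 P(\text{tie})$; the PRC area is the
  trapezoidal integral of precision over recall through the
  descending-score sweep with tied scores grouped, anchored at recall 0
  with the first point's precision. For multi-class labels both are
  prevalence-weighted one-vs-rest; a class absent from the truth
  contributes nothing, and a label whose pooled truth is single-class
  degrades to the chance value 0.5 with a warning.
* **Cross-validation.** `cv_fmll()` stratifies folds per label on that
  label's own target (stratification is only defined per target; a
  `shared_folds` switch aligns the sample space across labels when one
  partition must serve all). Indices are dealt round-robin per class under
  a single global cursor, so fold sizes differ by at most one — the first
  `n mod k` folds are the larger ones — and per-fold class counts deviate
  from proportionality by at most one instance. Test predictions are pooled
  over folds and each metric is computed once from the pooled vector
  (`pooling = "pooled"`, the default): pooling is invariant to unequal fold
  sizes, whereas averaging fold-wise metrics (`pooling = "foldwise"`, also
  available) weights small folds up. The report carries one row per label
  plus the unweighted (macro) `Average` row; accuracy renders in percent at
  2 decimals, rates at 3.
* **Method comparison.** `improvement_over_baselines()` is the plain
  difference between a proposed value and the unweighted baseline mean, in
  the input's units. `mann_whitney_u()` uses midranks for ties and an exact
  enumeration p-value for tie-free samples with $n+m \le 12$ (otherwise a
  normal approximation with tie and continuity corrections);
  `quade_test()` follows Conover's procedure — within-block ranks, block
  weights from the ranks of the within-block ranges, and an F reference
  with $(k-1, (b-1)(k-1))$ degrees of freedom. An all-tied table is a
  degenerate-input error; a perfectly consistent ordering (where the
  F statistic diverges) reports $p = (1/k!)^{b-1}$. Defaults are two-sided
  with automatic exact/approximate selection; published p-values from
  underdetermined inputs are never hard-coded anywhere in the package.

## The synthetic generator

`synth_generate()` draws features independently — numeric uniform over a
range, nominal/ordinal uniform over categories — and assigns each label by
a planted decision rule, then flips each label value to a uniformly random
class with probability `label_noise` (so a binary label disagrees with its
rule at rate `label_noise / 2`) and finally masks feature cells at
`missing_rate`. Everything is driven by one seed through R's
Mersenne-Twister with rejection sampling, with the caller's RNG state left
untouched, so fixtures are regenerated identically everywhere rather than
stored.

**Why decision-list rules.** Planted rules are decision lists (caterpillar
trees) of single-feature tests: numeric thresholds drawn from the middle
35–65% of the range, contiguous rank cuts for ordinal features, and
category-subset tests for nominal ones. Single-feature tests keep the truth
inside the REPTree hypothesis class; the *list* shape additionally keeps it
greedily recoverable. A balanced planted tree over binary labels with
alternating leaf classes is a parity function — every single feature has
exactly zero marginal information gain, so no greedy splitter can take the
first step, and reduced-error pruning would collapse any zero-improvement
split it did take. Recovery would then measure seed luck, not learner
correctness. With decision lists, every planted test has positive marginal
gain, making "the learner recovers the rule" a sharp, testable property. A
planted rule whose realized label is nearly constant (minority share below
5%) defines no classification task and is resampled within the seeded
stream.

**Preset shapes.** Three presets mirror the benchmark inventories this
method family is evaluated on, in shape only (no attempt to match marginal
statistics): `amphibians` — 189 rows, 3 numeric + 9 nominal + 2 ordinal
inputs, 7 binary presence labels; `anuran` — 7195 rows, 22 numeric acoustic
coefficients in $[-1, 1]$, labels with 4/8/10 classes; `adopt_a_buddy` —
18834 rows, 4 numeric + 2 nominal inputs, labels with 3/4 classes. Deep
multi-class labels may realize fewer classes than they declare at shallow
rule depths; declared inventories are preserved in the schema.

**What passing tests show — and what they do not.** The generator's
independence of features, uniform marginals, axis-aligned truth and
symmetric noise are exactly the assumptions under which a greedy
information-gain tree is well suited. Recovery results on synthetic data
therefore validate the *implementation* (decomposition, federation,
learner, evaluation bookkeeping), not the method's performance on real
surveys or call recordings, where features are correlated, classes are
imbalanced, and the truth is not a small tree. The published headline
accuracies on the real accessions are consequently not treated as
reproducible targets by this package's test suite.

## Numerical choices and tie-breaks

* Entropy in bits; gains must exceed $10^{-12}$ to count as positive.
* Equal-gain splits resolve to the earlier feature in schema order and the
  lower threshold; majority ties resolve to the earlier class in
  declaration order; the heaviest-child rule for missing values resolves
  weight ties to the earlier child. Together these make fitting exactly
  reproducible from (data, control).
* Fold assignment, the pruning partition, and all generator draws are
  seeded; identical inputs give byte-identical serialized models.
* Numeric values serialize (ARFF, JSON) at 17 significant digits, so
  write-then-read round trips reproduce doubles exactly.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the rule-recovery condition
at $n = 2000$ rows per preset shape with depth-3 rules and 10-fold CV
(recovered accuracy is typically above 99%, against a 95% bar), and the
noise-degradation comparison on five replicates of a small two-label
configuration at $n = 500$ with 5-fold CV. These sizes were chosen so the
whole pipeline — including the 18834-row-shaped preset scaled to 2000 —
exercises every code path in seconds while leaving the statistical
conclusions unambiguous.

## Known limitations

* No label-correlation modelling (BR by design); no classifier chains or
  ensembles.
* No fractional missing-value weighting, no split-threshold backfitting,
  and no bit-compatibility guarantee with other REPTree implementations.
* Multi-label-specific losses (Hamming loss, subset accuracy, ranking
  losses) are not reported; the report format is fixed to the
  per-label-plus-Average table.
* The federation is simulated in one process; nothing network-level is
  provided or claimed.
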