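---
title: "Methods: iterative self-distillation for assay-interference models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative self-distillation for assay-interference models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput screens are polluted by compounds that produce false
readouts without engaging the target: thiol-reactive electrophiles,
redox cyclers, and inhibitors of the luciferase detection systems
themselves. Classifiers that flag such compounds (quantitative
structure-interference relationship models, QSIR) are trained on small,
heavily imbalanced compound sets — a few thousand molecules with positive
rates between roughly 1.5% and 20% — which limits both their recall and
their precision.

`qsiraug` implements an iterative remedy: a teacher-student
self-distillation loop in which the current classifier steers a
goal-directed molecule generator toward putative interfering compounds,
an acquisition function selects a batch from the generated pool, the
batch is pseudo-labeled by the teacher, and a student is retrained on the
augmented set. After each iteration the student becomes the next teacher.

## The classifier

The QSIR model is a balanced random forest over Morgan fingerprints of
radius 3 folded to 2048 bits. Every tree is grown on a bootstrap drawn
with replacement that contains `n_min` compounds of each class, `n_min`
being the minority-class count; this is audited per tree
(`bootstrap_class_counts()`), not assumed. The predicted interference
probability `m(x)` is the fraction of trees voting for the positive
class. Using hard per-tree votes keeps three consumers consistent with a
single fitted forest: the probability itself, the vote matrix that feeds
the EPIG acquisition criterion, and the leaf matrix behind the
random-forest kernel.

Hyperparameters (`n_estimators` in 100–1000, `max_depth` unlimited or
4–32, `min_samples_split` 2–16, `max_features` sqrt/log2 or a fraction
0.1–1) are chosen by a seeded random search with 50 trials by default,
maximizing mean cross-validated MCC over stratified folds, and are then
frozen for every retraining inside the loop. MCC is the search objective
because it is the primary performance metric of the evaluation suite; the
trial table is retained as an attribute for inspection.

## Generation and reward

Generation is behind a protocol (`propose_molecules()`): any object that
accepts a reward scorer, a schedule, and a seed can drive the loop. The
reward is `f(x) = w1 * m(x) + w2 * wt(x)` with weights 0.8/0.2
(normalized), where `wt(x)` is a molecular-weight desirability equal to 1
on 160–480 Da. The window endpoints are a published drug-likeness range;
the 40 Da linear ramps outside it (reaching 0 at 120 and 520 Da) are a
package choice: they keep the score continuous and give optimizing
generators a gradient just outside the window. A full generation stage
runs 250 steps of 100 molecules (25,000 candidates) by default.

Two desk-scale stub generators implement the protocol:

* **Resampling stub** — samples a fixture pool with probability
  proportional to `exp(f(x)/tau)`, with `tau` decaying geometrically from
  1.0 to 0.2 across the schedule. The decay deliberately reproduces the
  qualitative signature of reward exploitation (falling internal
  diversity in later batches) in a controlled way.
* **Genetic-algorithm stub** — evolves genotypes of the synthetic
  fragment grammar (scaffold plus two substituents) with tournament
  selection, uniform crossover and per-gene mutation. An optional
  per-scaffold occurrence cap on the emitted pool plays the role of a
  diversity filter. The cap is keyed on the generator's own scaffold
  gene rather than the Murcko scaffold of the assembled molecule — that
  is where the generator can enforce it exactly and cheaply.

Pool bookkeeping follows two rules: the 25,000-molecule count is the raw
generated total, so duplicates are kept until acquisition time (where the
pool is deduplicated by canonical SMILES); and generated molecules whose
canonical SMILES exactly matches a test compound are removed before any
selection, so test information can never leak into training.

## Acquisition

Five strategies select `k = 250` molecules (default) from the
deduplicated pool via `A(x) = alpha * A_predictor(x) + beta * A_human(x)`:
random and greedy and EPIG with `beta = 0`, and GreedySkill/EPIGSkill
with `alpha = beta = 1`.

EPIG scores a candidate by the expected mutual information between its
predicted label and that of a random target molecule from the top-1000
pool molecules by `m(x)`. The forest supplies the joint distribution:
each tree is treated as one joint posterior sample, so
`p(y, y* | x, x*)` is the fraction of trees jointly voting `(y, y*)` and
the marginals are vote fractions. This same-tree pairing is the standard
ensemble-as-posterior-samples reading; it guarantees that any nonzero
joint cell has nonzero marginals, so the KL divergence (natural log) is
always finite, with `0 * log 0` defined as 0. The default estimator
averages 100 sampled targets per candidate; an exact all-pairs mode
exists and the tests verify the sampled estimator against it. Ranking
the target set by `m(x)` rather than by the full reward `f(x)` is a
deliberate choice (the two differ only through the weight score, which is
nearly constant over a well-formed pool); it is configurable through the
pool columns.

The expert component is pluggable. The default proxy is a deterministic
drug-likeness composite (QED minus penalties for more than eight
rotatable bonds and more than two heavy halogens). Because preference
models disagree about sign conventions, every scorer carries an explicit
orientation flag, and raw scores are min-max normalized within the
current pool before being combined — the pool is the only context in
which the two score scales have to be commensurable. A degenerate pool
(all raw scores equal) normalizes to 0.5 everywhere, which makes the
Skill strategies reduce exactly to their predictor-only counterparts.

Ties in any top-k selection are broken by canonical SMILES in C-locale
lexicographic order: deterministic, seed-independent, and logged via the
`tie_broken` attribute.

## Pseudo-labeling and augmentation

Acquired molecules are labeled by the *current* teacher at threshold 0.5
(boundary inclusive). Model-assigned labels, rather than a blanket
positive label, are the only reading consistent with tracking the
imbalance rate of the augmented set over iterations: both classes must be
able to enter. The threshold is configurable. On augmentation, molecules
already present in the training set keep their measured label
(pseudo-labels never overwrite data); collisions are reported. Any
overlap between an acquired batch and the test set is a hard error.

## The synthetic benchmark

Because the experimental interference sets cannot be shipped, the package
generates benchmarks with the same statistical shape: a few thousand
unique molecules, positive rates 1.5–20%, labels driven by planted
reactive substructures plus optional label noise. Molecules are
assembled from a fixed fragment grammar (24 ring scaffolds x 44
substituents); positives are defined by three SMARTS rules mirroring real
interference chemistry — an alpha,beta-unsaturated carbonyl (thiol
reactivity), a para-quinone (redox cycling), and a benzothiazole
(luciferin-like detection-system chemotype). With zero noise a
substructure search reproduces the labels exactly, which the tests use as
an oracle. The grammar deliberately contains near-miss decoys (saturated
carbonyl analogues, benzoxazoles, hydroquinones) so the decision boundary
is not a single fingerprint bit.

What the benchmark does *not* emulate: real chemical-space geometry
(grammar molecules are far more modular than screening collections),
activity cliffs, assay noise structure correlated with chemotype, or
multi-label interference. Passing the loop tests therefore demonstrates
that the machinery behaves as designed under controlled conditions, not
that equal gains will transfer to any particular experimental set.

Splits preserve class proportions exactly (floor allocation with
deterministic remainder placement), and the five cross-validation folds
partition the training set with per-class counts differing by at most
one.

## Model analysis

Teacher-student similarity is tracked with centered kernel alignment on
the random-forest kernel: `K[i, j]` is the fraction of trees in which
probe molecules i and j share a terminal node. The kernel is PSD by
construction (an average of block-indicator kernels; verified by
eigenvalue checks in the tests), the probe set is the held-out test set,
and the biased (plain Frobenius) HSIC estimator is used — debiasing
matters for small probe sets but the comparison is always at fixed probe
size here. A constant kernel centers to zero and has no defined
alignment; this is reported as `NA` rather than 0 or 1.

## Numerical conventions

* Tanimoto of two all-zero fingerprints is 1 (featureless duplicates
  should not look diverse).
* MCC with any zero denominator factor is 0.
* Enrichment factor is precision divided by positive prevalence
  `(TP+FN)/N`; with no predicted positives it is `NA` (undefined), never
  0. Its maximum `N/(TP+FN)` is attained at precision 1.
* Internal diversity normalizes the Tanimoto sum over all `|G|^2` ordered
  pairs (self-pairs included), which is what keeps the metric inside
  [0, 1]; radius-2/2048 fingerprints are used.
* PR-AUC is step-interpolated average precision (no trapezoids).
* PAINS counting uses the published 480-pattern catalog (families A, B,
  C) shipped as plain text; matching adds explicit hydrogens because the
  patterns reference `[#1]` atoms. Each molecule counts at most once.
* QED uses the published desirability parameterization over descriptors
  computed with Open Babel, with aromatic-ring counts derived from
  aromatic bond counts and a compact structural-alert list; values track
  but do not bit-match toolkits with different descriptor definitions.

## Problem sizes and defaults used in the shipped experiments

The packaged tests and the acceptance script run the loop at desk scale:
benchmarks of 800–2000 compounds, generation schedules of 20 x 25, 250
or 300 trees, k of 10–50, and 10 repetitions. These sizes were chosen so
a full replication is a coffee-break computation on one CPU while leaving
every mechanism (balanced bootstraps, reward-guided generation,
acquisition, pseudo-labeling, CKA tracking) exercised at full fidelity.
The full-scale defaults (25,000-molecule pools, k = 250, 50-trial
searches) remain the package defaults and are verified structurally with
a counting generator.

## Known limitations

* Fingerprints are binary (not counted), matching the 2048-bit
  convention; rare-environment collisions after folding are possible.
* The Murcko implementation prunes side chains and restores
  multiply-bonded framework attachments; it does not special-case exotic
  cage/spiro systems beyond what graph pruning implies.
* The stub generators cannot reproduce log-likelihood analyses of a
  trained generative policy; the generator protocol reserves an optional
  `log_likelihood` capability for adapters that have one.
* The expert proxy is a fixed heuristic; it stands behind the same
  interface an external preference model would use, and its scores are
  only meaningful after within-pool normalization.
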