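---
title: "Dynamic-clustering active learning for e-nose drift: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-clustering active learning for e-nose drift: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftal)
```

This vignette is the package's own account of its science: the selection
model and its assumptions, the parameters that matter, what the
synthetic benchmark does and does not emulate, and the numerical and
design choices made where the problem was genuinely open.

## The drift-compensation setting

A gas-sensor array's response distribution moves over time. We model
deployment as an ordered sequence of *batches*: within a batch the
distribution is treated as stationary; between batches it drifts. The
classifier (the *learner*) starts from a fully labeled initial batch.
For every later batch only the feature vectors arrive; a labelling
oracle (an expert, or a reference assay) can be queried instance by
instance at a fixed per-label cost. An active-learning round spends a
budget of `n_select` queries on the batch's *data pool* and retrains the
learner after every query.

The working assumption behind every selector here is that the drifted
batch is informative about the *current* decision problem, so labels
spent inside it repair the learner faster than any label-free
correction. The dynamic-clustering selector adds a second assumption:
**instances in the same pool cluster share a class**, provided the
clustering is seeded near the true class centers. That is what justifies
balancing queries across clusters as a label-free surrogate for
balancing them across classes.

## The selectors

All selectors consume a strictly positive per-instance uncertainty
`I(x)`:

* uncertainty sampling: `I = 1 − margin + ε`, margin = top-1 minus top-2
  posterior;
* query-by-committee: `I = KLD + ε`, the mean Kullback–Leibler
  divergence of each member posterior from the committee consensus
  (natural logarithm, `0·log 0 := 0`);
* error reduction: `I` is the current pool loss minus the expected pool
  loss after hypothetically labeling the candidate, the expectation
  taken over the candidate's current posterior, clamped below at `ε`.

The dynamic-clustering loop re-seeds a Lloyd clustering of the pool from
the per-class means of the *current* training set at every iteration,
ranks clusters by mean uncertainty under a binary flag mask, picks the
most uncertain instance of the winning cluster, and clears that
cluster's flag; the mask resets when exhausted. Two consequences are
guaranteed by construction and verified by the test suite: within one
flag cycle no cluster is picked twice before every non-empty cluster has
been picked once, and the within-cluster sum of squares never increases
across clustering iterations.

The adaptive confidence rule uses the committee's KLD but alternates
between boundary picks (max KLD) and class-center picks (min KLD): if
the chair's predicted labels on the pool changed in the last update the
boundary is still moving and a boundary instance is taken, otherwise a
representative center instance is. The first pick of a round, having no
previous update, takes the boundary branch.

## Learner and calibration

The reference learner is a kernelized extreme learning machine:
`k(x,y) = exp(−γ‖x−y‖²)`, output weights `β = (K + I/C)⁻¹ T` with
one-hot targets `T`. With `C > 0` the system is symmetric positive
definite, so the solve is always well posed. Posteriors are the softmax
of the decision scores — the simplest monotone map from scores to the
simplex; no Platt-style recalibration is attempted. A consequence worth
knowing: duplicating every training sample is *exactly* equivalent to
doubling `C` (the test suite asserts this identity), so posteriors are
invariant to dataset duplication only in the large-`C` limit.

Parameters, defaults, and rationale:

| parameter | default | meaning / rationale |
|---|---|---|
| `gamma` | 0.005 | RBF width on benchmark-scale (128-dim) features; the conventional setting for this data family. Interpreted as the multiplier of the squared distance; if your source quotes an inverse width, convert. |
| `C_reg` | 100 | ridge constant; large enough to fit separable batches, small enough to keep solves well conditioned |
| `k_members` | 2 | committee size for QBC/ACR; members are stratified bootstrap resamples (fraction 1, with replacement, drawn within class so no class ever disappears) |
| `n_select` | 20 | labels per round; the useful lower bound is the class count `K`, since a full-category update is what restores a drifted learner fastest |
| `pool_fraction` | 1/3 | pool:test split of each drifted batch, the conventional ≈1:2 ratio; a `whole_batch` mode uses the full batch as both pool and evaluation target |
| `metric$pool_cap` | 200 | ER evaluates hypothetical retrains on a seeded subsample of the pool beyond this size; exact ER retrains `|pool| · K` learners per candidate and is kept for tests |
| `alpha` | 0.5 | label-efficiency blend `LEI = α·A + (1−α)·ΔA`; equal weight on level and increment |
| `tol`, `max_iter` | 1e-6, 100 | clustering convergence: max centroid displacement below `tol`, hard cap at `max_iter` |

## Numerical choices

* **Tie-breaking** is everywhere "lowest index": nearest-mean
  assignment, cluster selection, within-cluster selection, and global
  argmax/argmin picks.
* **Degenerate clusters**: an empty cluster keeps its previous mean and
  is never selectable (its mean score is treated as −∞). If every
  *flagged* cluster is empty the flag vector is reset rather than
  deadlocking.
* **Round-off ties in disagreement**: committee members fitted on
  near-identical resamples produce KLD values at the 1e-16 level that
  are mathematically zero. The selection layer snaps disagreements below
  1e-12 to exactly 0 so that such ties resolve by index instead of by
  floating-point noise (1e-12 is also the threshold at which the
  KLD-of-identical-members invariant is asserted).
* **Positivity floor** `ε = 1e-12` keeps every `I(x)` strictly positive,
  as the cluster-ranking rule requires; ER scores whose expected
  reduction is negative are clamped to `ε`.
* **Normalization** (off by default) is a z-score with location and
  scale estimated on the initial training batch only — denominator-`n`
  standard deviation, constant features mapped to 0 — and applied
  unchanged to all later data, so no pool or test information leaks into
  the transform.
* **Determinism**: one master seed; every stochastic step (splits,
  bootstrap resamples, ER subsampling, random selection) derives a child
  seed from the master seed plus a step key, making whole protocol runs
  bit-for-bit reproducible.

## Feature extraction

Each sensor's transient contributes 8 features: the steady-state
response change `ΔR = max(r) − r[0]`, its baseline-normalized version
`ΔR / r[0]`, and, for smoothing coefficients `a ∈ {0.1, 0.01, 0.001}`,
the maximum over the rising stage and the minimum over the decaying
stage of the exponentially smoothed increment series
`y[k] = (1−a)·y[k−1] + a·(r[k] − r[k−1])`, `y[0] = 0`. A 16-sensor array
therefore yields 128 features. Conventions the source material leaves
open were fixed as follows: the rising/decaying boundary defaults to the
response peak (clamped inside the record so constant traces degrade to
all-zero features rather than erroring); `ΔR` is baseline-relative; the
rise aggregate is a signed max and the decay aggregate a signed min,
matching the originating benchmark's usage. A zero baseline makes the
normalized feature undefined and raises an error.

## The synthetic benchmark: what it emulates, and what it does not

`drift_spec()` defaults define the package's study conditions: K = 6
classes, 10 batches of 150 samples, D = 8 dimensions, class means drawn
with per-coordinate spread 3 and unit within-class noise, per-batch
drift = a shared unit direction scaled by 1.2 plus a per-class random
direction scaled by 0.6, small per-batch jitter (0.05), and
Dirichlet(1)-distributed per-batch class proportions floored at 2
samples per class. These values were fixed, once, to match the
observable shape of real long-term e-nose drift data: classes nearly
separable within a batch (a batch-1 holdout learner is at ≈100%),
batch-to-batch class imbalance that varies strongly, and a
never-updated learner losing tens of accuracy points by batch 10. The
`batch10_break` preset adds a five-fold extra jump at the last batch,
mimicking the collapse seen after a long recording gap. D = 8 keeps the
30-replicate simulation studies (9 rounds × 20 queries × 4 strategies
each) around a minute of CPU; D = 128 is available when benchmark-sized
vectors matter.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data:

* *Within-batch class overlap.* Gaussian blobs at these settings have
  essentially zero Bayes error inside a batch, so any selector that
  covers all classes saturates near 100% after updating; real chemical
  data retains irreducible confusion between similar volatiles. One
  visible consequence: plain uncertainty sampling — which under an RBF
  kernel assigns near-uniform posteriors to instances far from all
  training data, and hence never starves a drifted class — ties with the
  dynamic-clustering variant at the final-accuracy endpoint here. The
  clustering selector's advantages that *are* measurable on this
  benchmark are class coverage of the first K queries and the gaps over
  random and static selection.
* *Nonlinear drift.* Mean translation plus jitter; no rotation, scale
  change or sensor-specific decay.
* *Sensor physics.* The transient simulator produces idealized
  rise/decay exponentials for exercising the extractor, not a chemistry
  model.

## Protocol design decisions

* **Long-term accumulation.** Queried samples stay in the training set
  across rounds (a deployed system keeps labels it paid for); a
  no-accumulate mode exists for ablation.
* **Pool/test overlap.** Published drift-benchmark tables are ambiguous
  about whether test sets include the pool. Both a disjoint stratified
  split (default) and a `whole_batch` mode (pool = evaluation target =
  full batch) are provided rather than guessing.
* **Evaluation mode.** Accuracy is reported on the test partition by
  default; a `pool_plus_test` mode pools correct counts of the remaining
  (unqueried) pool and the test set.
* **Class means** are recomputed from the cumulative training set each
  iteration, matching the loop structure in which initialization
  re-executes after every training-set update; a freeze-clusters mode
  trades fidelity for speed.
* **ACR's comparison target** is the chair's predicted labels on the
  current pool before vs after the retrain (the natural pool-wide
  reading of "outputs of the chair").
* **LEI reporting.** `A` is the test accuracy before the N-th update and
  `ΔA` the increment that update caused; values are averaged over the
  protocol's rounds. The sweep over budgets exploits that greedy
  sequential selection does not depend on the total budget: one run at
  `max(N)` is sliced per `N`.

## Known limitations

Beyond the generator's idealizations above: ER is `O(|pool| · K)`
retrains per candidate and depends on the subsampling cap for large
pools; the kernel ELM is refit from scratch after every query (no
incremental updates), which is exact but quadratic-to-cubic in the
training size; and committee construction for QBC under-determines the
published method, so the stratified-bootstrap choice here, while
conventional, is one of several defensible designs.
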