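---
title: "The dualmem model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dualmem model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dualmem)
```

## The model in brief

`dualmem` simulates early object categorization with two interacting
auto-encoders that share one input. Each component is a three-layer
logistic network that reconstructs its 18-feature input through a 15-unit
hidden bottleneck, forcing it to extract the regularities of the object
world. The *hippocampal* component learns fast and models on-line category
formation in familiarization (looking-time) studies; the *cortical*
component learns slowly and models long-term representational development.
Their hidden layers exchange activation through two trainable
cross-connection matrices, and optional label (task) units read out from
the cortical hidden layer — a label is a supervised mapping *from*
perceptual representations, not an additional input feature.

The linking hypothesis to behaviour is reconstruction error: the
hippocampal summed squared error for a stimulus stands in for an infant's
looking time at it (`looking_time()`), and familiarization-to-criterion is
the number of presentations until that error falls below a threshold.

## Forward dynamics: settling

On presentation of an object $x$, each hidden layer receives a fixed input
drive $W^{in} x + b$ plus cross input from the other component's hidden
state. The two hidden vectors are updated synchronously through the
logistic function until no activation changes by more than `settle_tol`
(default 1e-4, capped at `settle_max_iter = 50` iterations; non-convergence
is flagged, not an error). With the default weight scale (uniform ±0.5) the
iteration is strongly contractive: across the whole default corpus it
settles in at most ~7 iterations. An optional damping factor is available
for stiffer weight configurations. With cross-connections at zero, settling
reduces exactly to each component's single feed-forward pass, which the
test suite asserts.

## Learning

Every presentation applies one online backpropagation step of the summed
squared error over both reconstructions (plus the task term when a label is
shown, with a one-hot target and weight 1 in the objective). Two choices
deserve comment:

* **Gradient treatment of the recurrence.** The settled hidden state is
  treated as an ordinary feed-forward hidden layer: each cross-connection
  block receives the gradient of the final settling step only, with the
  other component's settled state held fixed. There is no backpropagation
  through the settling iterations. This is the simplest scheme consistent
  with "update all weights by backpropagation", and it makes the update an
  exact gradient of a well-defined linearized objective — which is what the
  finite-difference tests verify, to ~1e-7 relative error.

* **Learning-rate assignment.** Each component's own weights move at its
  rate (`lr_hip = 0.02`, `lr_cor = 0.01` by default); task weights move at
  the cortical rate (they attach to the cortical hidden layer). For the
  cross-connections the package defaults to the *recipient* rule: the block
  feeding a component's hidden layer learns at that component's rate, so
  the fast hippocampal system also binds quickly to the cortical signal it
  receives. This choice is behaviourally decisive: with both cross blocks
  at the slow cortical rate, labelled background experience fails to
  propagate any advantage to the hippocampal readout during
  familiarization (the labelled-vs-unlabelled contrast sits at chance),
  whereas under the recipient rule the label advantage expresses reliably.
  The alternative is available as `cross_lr = "cortical"`.

The learning-rate *values* are calibration choices, exposed in
`model_config()`. The asymmetry `lr_hip > lr_cor` is the model's core
assumption and is enforced (equality is allowed so that zero-rate null
tests are expressible). The 2:1 default ratio was chosen because it
realizes both headline phenomena at the 4000-presentation budget: with a
much faster hippocampal rate (e.g. 0.1) familiarization completes within a
handful of cycles and is insensitive to the subtler, label-driven cortical
differences; the familiarity effect survives but the label effect cannot
express. Nothing in the implementation depends on the specific values.

When no label is presented, the task weights are not updated at all — not
trained toward a zero target. Unlabelled training therefore leaves them
bit-identical, which is asserted exactly.

## The stimulus generator

The original corpus measured 18 geometric and facial features from
photographs of 26 basic-level categories (8 exemplars each) nested in four
global-level categories; those measurements are not published. The
generator reproduces the *similarity structure* the model consumes rather
than the feature identities: one latent anchor per global category (uniform
in [0.2, 0.8] per dimension, keeping Gaussian jitter mostly inside the unit
interval), basic-level generating prototypes scattered around their anchor
(`sigma_global = 0.15`), and exemplars jittered around their prototype
(`sigma_basic = 0.05`), everything clipped to [0, 1]. Clipping (rather than
resampling) introduces negligible bias at these spreads. The three facial
dimensions of vehicles and furniture are drawn near zero, giving inanimates
the systematic feature difference from animates that real photographs would
show (toggleable via `faceless_near_zero`). Category prototypes used in the
analyses are the *empirical* feature means of each category's exemplars,
computed by `compute_prototypes()` and held out of the training set.

What the generator does **not** emulate: correlated feature dimensions,
category-specific variability profiles (uniform `sigma_basic` by default,
with per-category overrides available), and the idiosyncratic cross-global
similarities of real objects (a plane and an eagle sharing wing-like
protrusions). Passing tests therefore show that the *mechanisms* behave as
claimed on hierarchically structured input, not that the model reproduces
any particular photograph-derived layout.

## Training regimes

*Background training* simulates everyday experience: draw a non-excluded
object uniformly, draw an encounter length uniformly in
`[exposure_min, exposure_max]` (default 1–1000 update steps), toss the
labelling coin once per encounter (probability 0.5), and apply one online
update per step. The labelling coin is tossed even when the scheme shows no
labels, so paired conditions see identical object streams. One "epoch" of
exposure is read as one online update on that object — with per-
presentation online learning there is no other natural unit.

*Familiarization training* presents the test items cyclically without
labels, evaluating the mean hippocampal error over the set after each full
cycle (weights frozen during evaluation); it stops when the mean first
falls below `criterion` (default 0.05 summed squared error, i.e. ~0.05
mean absolute deviation per feature) or at `max_presentations` (default
10000, flagged unconverged). The criterion applies to the set mean — the
paradigm familiarizes six items against one criterion — with a per-item
variant available. Both components keep learning during familiarization,
each at its own rate; only the hippocampal error is read out.

## The two experiments

Both experiments are paired multi-seed designs: conditions within a seed
share initial weights (the task block is drawn last, so models differing
only in `n_task` share all other weights) and identical presentation
streams. Effects are tested with an exact sign test on paired per-seed
differences — distribution-free and honest at n = 10 — alongside paired
means.

The *warping* experiment trains one model without labels and one with
global-level labels for 4000 presentations and compares the silhouette of
the 26 prototype representations grouped by global category. Separation is
computed in the full 15-dimensional hidden space; the 2-D PCA projection is
for visualization only, avoiding projection artifacts in the quantitative
claim. PCA is fit separately per condition. The 4000-step budget is spread
over the corpus as single-step presentations: with the generic 1–1000
encounter lengths a 4000-step budget would expose the model to only ~8
distinct objects, which probes encounter-length variability rather than
labelling.

The *familiarization* experiment compares presentations-to-criterion on six
held-out rabbits after (A) no background, (B) unlabelled background on all
objects minus the held-out rabbits (two rabbits remain), and (C) the same
background with basic-level labels. Condition A starts from freshly
initialized weights with no pre-exposure of any kind. At the defaults the
familiarity effect (A > B) is large (~70 of ~250 presentations) and held in
10/10 seeds at the default base seed; the label effect (B > C) is a
second-order effect an order of magnitude smaller (~5 presentations, ~3%),
held in 9/10 seeds at the default base seed but fluctuating between 6/10
and 9/10 across other seed windows. This size ordering is expected: labels
influence the hippocampal readout only indirectly, through the settled
cross-talk with the warped cortical representations.

## Numerical and interface choices

* Weights are initialized uniformly in ±0.5 and drawn in a fixed block
  order (task last) for cross-condition pairing; all generation and
  training is bit-reproducible per seed, and package functions never
  disturb the caller's RNG state.
* Per-replicate seeds derive from one base seed with fixed offsets for the
  stimulus, model, and training streams.
* Silhouettes use `cluster::silhouette` (singletons contribute width 0);
  tests verify against a definitional re-implementation. PCA uses
  `stats::prcomp` with a fixed sign convention (largest-magnitude loading
  positive) for cross-platform reproducibility.
* Degenerate geometries are flagged rather than erroring: coincident points
  give silhouette 0 and an undefined between/within ratio; zero within-
  group dispersion with separated centroids gives an infinite ratio.
* JSON serialization (models, configs, summaries) prints doubles with 17
  significant digits so that save/load and config replay are exact; result
  CSVs carry the resolved-config hash, and replaying an emitted resolved
  config reproduces them bit-identically.
* Experiment sizes (10 seeds, 4000-step budgets) are the package defaults
  chosen to keep a full paired experiment in the order of a minute on one
  CPU while leaving the sign test enough resolution; all are raisable in
  config.

## Known limitations

* The generator's abstract features cannot reproduce item-level layouts of
  real-photograph feature spaces; only structural claims are tested.
* The labelled-background familiarization advantage is small at the default
  calibration and its per-seed sign consistency varies with the seed
  window; the mean advantage is stable in direction.
* No backpropagation through settling means the cross-connection gradients
  are local to the settled state; with strongly non-contractive weights
  (large `init_range`) settling may fail to converge and results are
  flagged rather than corrected.
* Habituation criteria used with real infants (e.g. proportion-of-initial-
  looking rules), attention and arousal dynamics, and batch or replay-based
  consolidation are out of scope.
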