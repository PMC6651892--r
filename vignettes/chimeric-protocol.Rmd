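---
title: "Building and evaluating menagerie-constrained chimeric biometric datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating menagerie-constrained chimeric biometric datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChimeraZoo)
```

## The problem

Multimodal biometric evaluation needs datasets in which the same subjects
are captured across several traits (say, face, periocular region, and
off-the-person ECG). Such datasets are rare, so researchers build *chimeric*
datasets: virtual subjects assembled by pairing one real individual per
modality from unrelated unimodal datasets. Done with unconstrained random
pairing, the assembly can concentrate the difficult subjects unevenly — one
run pairs an easy face with an easy heartbeat, the next pairs two
pathological cases — and fusion comparisons on such datasets are noisy and
hard to reproduce.

ChimeraZoo implements a constrained, fully seeded construction. Each
modality's individuals are first labeled with the Doddington-Zoo menagerie:

* **sheep** — typical subjects, the majority;
* **goats** — subjects with high intra-class variability, hard to match;
* **lambs** — subjects with low inter-class separation, easy to imitate.

(The fourth animal, the *wolf* — an active impersonator — belongs to
spoofing analyses and is out of scope here.) Chimeric individuals then
combine only like-labeled sources, so every virtual subject has a coherent
difficulty across its modalities, and every random stage records its seed.

## Zoo labeling

Labeling uses training-session data only (the first session of the declared
session order; the later sessions are probe data and must not leak into the
difficulty estimate).

* The **goat statistic** of individual $j$ is the mean distance over all
  unordered pairs of $j$'s training samples (intra-class dispersion).
* The **lamb statistic** is the mean distance between each of $j$'s
  training samples and every training sample of every other individual
  (one-against-all inter-class distance).

Individuals missing any session are discarded first. With $N$ valid
individuals, ranked ascending by a statistic, the percentile index

$$\mathrm{index} = \frac{p}{100}N + \frac{1}{2}$$

is evaluated exactly. Goat candidates are the ranks strictly above the
index at $p = 70$ (for $N = 56$: index $39.7$, ranks $40..56$, 17
candidates); lamb candidates are the ranks up to the round-half-up of the
index at $p = 30$ (for $N = 56$: index $17.3$, 17 candidates). Rank ties
are broken by individual id so that labeling is deterministic and
order-insensitive. An individual qualifying for both lists is resolved to
goat; the two lists must not overlap in the final labeling, and goat status
is the rarer, more consequential condition for verification error.

From each candidate list a seeded random permutation keeps
$\mathrm{roundHalfUp}(0.10\,N)$ individuals (capped at the list length);
everyone else is a sheep. The 10% count, rather than a second percentile
formula, matches the fixed per-category counts the combination constraints
require, and guarantees sheep remain the strict majority — violating that
is an error, not a warning. Re-running with a new seed selects a different
subset of the candidates, which is what makes repeated evaluation runs
draw different but equally difficult chimeric datasets.

When several modalities originate from the *same* individuals, labels are
reconciled rather than drawn independently: ids labeled identically across
modalities keep that label, and if a minority category falls short of its
target count, the divergently labeled ids are pooled, permuted under the
configured seed, and used to fill the category.

## Building chimeric individuals

Per category, the number of chimeric individuals is capped at the modality
with the fewest individuals of that category — combining (10 goats, 10
lambs, 80 sheep) with (5 goats, 5 lambs, 400 sheep) yields 5 goats, 5
lambs, 80 sheep. Within each category, each modality's individuals are
permuted under a stage seed and paired positionally, so assignment is
injective: a source individual feeds at most one chimeric individual, and
unselected individuals are simply unused.

Samples are paired sequentially *within sessions*: the $k$-th
training-session sample of modality 1 joins the $k$-th training-session
sample of modality 2, and likewise for the test session; the per-session
sample count of a chimeric individual is the minimum across its sources.
Pairing across sessions would silently corrupt the inter-session scenario
(a "training" chimeric sample would contain probe-session data in one
modality), which is why the builder never mixes sessions even though a
flat sequential pairing would be simpler.

Every build emits a `BuildRecipe`: the master seed, the derived stage
seeds, and the concrete outcome of each random stage. The recipe
serializes to JSON, and `replayRecipe()` reconstructs the identical
dataset, so a published recipe plus the source feature tables reproduce an
experiment exactly.

## Matching, fusion, and metrics

Matching works in dissimilarity space throughout: Euclidean, Manhattan,
Spearman ($1-\rho$, midranks for ties), and Hamming (fraction of differing
coordinates) distances, with a probe accepted when its minimum distance to
the claimed identity's gallery falls below the threshold. Mahalanobis is
deliberately not offered: it requires a covariance estimator whose choice
(pooled, per-class, shrinkage) would dominate the results and is not part
of this protocol.

Fusion happens at two levels:

* **feature level**: per-modality vectors are min-max scaled per dimension
  with training-session statistics and concatenated (an $n$-dimensional
  and an $m$-dimensional modality give $n+m$ dimensions);
* **score level**: per-modality distances are min-max normalized onto
  $[0,1]$ over the union of genuine and impostor scores of the current
  evaluation run, then combined by the `sum`, `min`, or `mult` rule.

The normalization step is a deliberate design choice: the raw distance
scales of different modalities (and different metrics) are not
commensurable, and sum/min/product are all scale-sensitive. Min-max over
the run's own scores is order-preserving per modality, so it cannot change
any unimodal ranking; it only puts the modalities on a common footing.

Separation of the genuine and impostor score distributions is summarized
by the decidability

$$d' = \frac{|\mu_E - \mu_I|}{\sqrt{(\sigma_I^2 + \sigma_E^2)/2}},$$

computed from sample moments, and by the DET curve and its equal error
rate. The DET curve sweeps a threshold over every distinct score (plus
infinite sentinels): FAR is the fraction of impostor scores strictly below
the threshold, FRR the fraction of genuine scores at or above it. The EER
is located by linear interpolation between the two adjacent thresholds
where FAR − FRR changes sign — stable for small pair counts, where the
nearest-point convention can be off by half a step. Decidability is
invariant under common affine rescaling of scores, and EER under any
strictly monotone transform; both invariances are asserted in the test
suite.

## Scenarios and the repeated protocol

Three evaluation scenarios are enumerated:

* `train_intra`: all unordered pairs within the training session;
* `test_intra`: all unordered pairs within the test session;
* `inter`: the full cross-product of test (probe) × training (gallery)
  samples, so every pair spans sessions.

Because the dataset construction is stochastic, a single build proves
nothing. `runProtocol()` repeats the entire pipeline — fresh stage seeds,
fresh labeling permutations, fresh assignment, fresh evaluation — 30 times
by default, all derived deterministically from one master seed, and
reports mean ± sd of decidability and EER per method and scenario.
`compareMethods()` then tests every method's per-run EERs against the
lowest-mean-EER method. Welch's unequal-variance two-sample t-test is used
rather than the pooled-variance Student form: run variances differ
visibly between unimodal and fused methods, and Welch is the safe default
that coincides with the pooled test when variances happen to agree.

## The synthetic generator

The generator exists so the whole protocol is testable end to end without
any external biometric data. Each individual of a modality draws a class
center from a spherical Gaussian (scale `sigmaBetween`); each
(individual, session) adds a drift offset (scale `sigmaDrift`); each
sample adds within-class noise (scale `sigmaWithin`). Planted goats have
their within-class noise multiplied by `goatMultiplier`; planted lambs
have their center shrunk toward the origin — the population mean — by
`lambShrink`, which directly lowers their one-against-all distance.
Session drift is what makes the inter-session scenario harder than
intra-session, mirroring real acquisition campaigns separated by weeks.

Defaults, chosen once as a plausible emulation of embedding-space
biometric data and kept fixed: three 16-dimensional modalities,
`sigmaBetween = 1`, `sigmaWithin = 0.5`, `sigmaDrift = 0.3`, two sessions,
3–6 samples per individual per session, 10% planted goats and 10% planted
lambs, `goatMultiplier = 2`, `lambShrink = 0.5`. The multiplier and shrink
deserve a note: at the default geometry, a multiplier as large as 5 makes
a goat's genuine distances *exceed* typical impostor distances — such an
individual is not a hard user but an unusable sensor, and score fusion of
three such modalities concentrates the hopelessness instead of averaging
noise away. The defaults keep goats and lambs clearly harder than sheep
while still better than chance, the regime in which the menagerie
constraints and fusion are both meaningful. The label-recovery tests use
the stronger settings (`goatMultiplier = 5`, `lambShrink = 0.1`)
explicitly, where planted animals should be recovered by the percentile
statistics at 90%+.

What the generator does *not* emulate: heavy-tailed or manifold-structured
embeddings, correlated feature dimensions, class-dependent drift,
acquisition failures, or adversarial (wolf) subjects. Passing tests on
synthetic suites therefore validate the protocol's mechanics —
labeling, capping, injective assignment, seeded reproducibility, metric
arithmetic, and the direction of fusion effects — not absolute error rates
on any real modality.

## Numerical conventions and edge cases

* Fractional ranks are converted with round-half-up (`floor(x + 0.5)`);
  R's banker's rounding would make counts depend on parity.
* Sorting ties (equal statistics) break by id; all outputs are invariant
  to input record order.
* Min-max normalization of constant scores, Spearman on constant vectors,
  and decidability of two identical constant distributions are errors with
  dedicated condition classes, not silent NaNs.
* Feature dimensions with zero training range scale to 0 in concatenation
  (they carry no information).
* Stage seeds derive from the master seed via one `sample.int()` draw per
  named stage under the master-seeded RNG; the RNG state of the caller is
  always restored.

## Problem sizes

The shipped tests run the full protocol at deliberately modest sizes —
suites of 10–16 individuals for builder invariants, 40–48 individuals ×
three modalities × 30 runs for the fusion direction-of-effect check, and
$10^5$ sampled score pairs for the Gaussian EER and $\sqrt{m}$ fusion
checks — sizes at which every statistical assertion is already stable
across seeds while a complete run of the suite stays fast on one CPU.

## Limitations

Chimeric datasets, however constrained, are stand-ins: results on them
need not transfer to datasets where all modalities are captured from the
same people, and the menagerie constraint deliberately builds a
worst-case-leaning population. The protocol evaluates verification
(open-set, one-to-one) only; closed-set identification is out of scope, as
are trainable fusion rules and the max / exponential-sum score rules.
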