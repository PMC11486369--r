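---
title: "Transfer-entropy connectivity and network features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer-entropy connectivity and network features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teconnect)
```

## The problem

Autism spectrum disorder (ASD) and attention-deficit/hyperactivity
disorder (ADHD) overlap heavily in symptoms, and separating them from
each other — not just from typically developing (TD) controls — is a
three-class problem. One productive line of work extracts ROI-level BOLD
time series from resting-state fMRI, measures directed statistical
coupling between regions, and classifies subjects from the resulting
connectivity matrices, using complex-network summaries of the same
matrices to interpret what differs between groups.

`teconnect` implements that analysis chain as a tested, reusable
pipeline: directed connectivity by normalized transfer entropy, a
multiclass evaluation harness, network-feature extraction including
effective information, and an interpretation layer. Because the original
imaging cohorts (ABIDE, ADHD-200) require large external downloads, the
package ships a synthetic-cohort generator with planted,
recoverable group structure, so every stage can be exercised and
verified end to end on a desktop.

## Transfer-entropy connectivity

Each channel of a window is min-max normalized to [0, 1] and binarized
at 0.5 (value >= threshold maps to 1). For binary symbol series the
transfer entropy from source $Y$ to target $X$ at lag $\tau$ is the
plug-in estimate

$$ TE_{Y \to X}(\tau) \;=\; \sum P(x_{t+\tau}, x_t, y_t)\,
   \log_2 \frac{P(x_{t+\tau} \mid x_t, y_t)}{P(x_{t+\tau} \mid x_t)} , $$

with empirical frequencies over the $N - \tau$ observed triples and the
$0 \log 0 = 0$ convention. We report the *normalized* transfer entropy,
TE divided by the plug-in conditional entropy $H(x_{t+\tau} \mid x_t)$
of the target. The plug-in TE never exceeds that conditional entropy, so
the ratio lies in [0, 1]; it equals 1 when the source makes the target's
next symbol fully predictable and 0 when the source adds nothing. The
degenerate 0/0 case (a target already fully predictable from its own
past) maps to 0.

Choices a user can change, with defaults:

* `tau = 1` sample. The coupling lag is not identifiable from the data
  contract; one sample is the natural default for TR-resolution series.
* `window_seconds = 20`, `stride_seconds = 20`. Twenty-second windows
  provide data augmentation (15 windows from a 300 s series at TR 2 s);
  the stride defaults to the window length, i.e. non-overlapping
  windows, so windows share no samples.
* `binarize_threshold = 0.5` on the min-max normalized series. The
  estimator is built for binary symbols; 0.5 splits each window's range
  symmetrically.
* The time series are binarized before TE; the TE matrix itself stays
  real-valued for the classifiers. Thresholding the matrix instead is
  available through `to_graph()` for the network-feature stage.

Windows containing a constant channel cannot be min-max normalized;
they are skipped with a message rather than imputed.

The estimator is verified against an independently coded brute-force
triple enumeration (agreement to 1e-12 on random inputs) and against
analytic limits: a lag-1 deterministic copy of a fair binary source
gives TE → 1 bit and normalized TE → 1; independent sources give
normalized TE below 0.01 at $N = 10^4$, a ceiling established by a
Monte-Carlo run of the estimator on independent pairs (the plug-in
estimator is positively biased at finite $N$; at $N = 10^4$ the bias is
~1e-4 bits, at 9 samples per 20 s window it is ~0.25 bits — which is
why group statistics run at subject level, below).

## The evaluation protocol

The 600 selected window matrices (200 per class) are vectorized over
the 380 ordered ROI pairs. The protocol then mirrors standard practice:

1. A stratified 30% hold-out (180 matrices, 60 per class) is reserved
   before any training decision.
2. Stratified, shuffled 10-fold cross-validation on the remaining 420;
   standardization (zero mean, unit variance, population convention) is
   re-fitted inside every fold, never on held-out data.
3. Exhaustive grid search scored by mean CV accuracy (ties broken by
   grid order), then the winner is refitted on the full training set.
4. Hold-out evaluation: accuracy, support-weighted precision and recall
   (the averaging convention is stated because it is not standardized in
   the literature), per-class one-vs-rest ROC AUC, the micro average
   (pooling all class-instance decisions) and the macro average
   (unweighted mean of per-class AUCs).

Robustness probes: recursive feature elimination with a linear SVM
(features ranked by the squared one-vs-one weight sums, 10 dropped per
iteration); a learning curve over stratified subsample sizes; an
additive-noise sweep (Gaussian noise of increasing mean, sd fixed at
0.1, added to the *raw* test features and passed through the
already-fitted standardizer — the fitted transform is part of the
deployed model, so noise must pass through it); and a k-sweep over
k ∈ {2, 3, 5, 10, 15}. A label-shuffled control verifies the chance
floor, and a pure-noise canary verifies that no preprocessing statistic
leaks across folds.

## Network features and effective information

Each connectivity matrix is thresholded at 0.5; the surviving directed
weights define the random-walker dynamics, and their OR-symmetrized
unweighted version feeds the 17 global measures (average shortest path
length, betweenness, closeness, diameter, assortativity, hub score,
eccentricity, eigenvector centrality, average neighbor degree, mean
degree, degree-distribution entropy, transitivity, second moment of the
degree distribution, complexity = ⟨k²⟩/⟨k⟩, k-core, density,
efficiency). Node-level measures are reduced to the node mean;
path-based measures use the largest connected component. Degenerate
cases follow fixed conventions (single-node component: APL = efficiency
= diameter = 0; undefined assortativity or transitivity recorded as 0)
so a feature table never fails on an unlucky window.

Seven community-detection algorithms (fast-greedy, infomap,
leading-eigenvector, label-propagation, edge-betweenness, spin-glass,
multilevel) are each reduced to one scalar: the average path length
inside the largest community they find. Stochastic algorithms consume
derived seeds; an algorithm inapplicable to a particular graph (e.g.
spin-glass needs a connected graph) falls back to the whole-component
APL with a note.

Effective information summarizes the walker dynamics on the `n`
out-active nodes: *determinism* is $\log_2 n$ minus the mean entropy of
the per-node out-weight profiles (how concentrated each node's outputs
are); *degeneracy* is $\log_2 n$ minus the entropy of the average
profile (how much different nodes' outputs pile onto the same targets);
EI = determinism − degeneracy. Closed forms on canonical graphs anchor
the implementation: a complete graph with self-loops has EI = det = deg
= 0; a directed ring has EI = det = log2 n and deg = 0; an all-to-hub
star has det = deg = log2 n and EI = 0. Restricting $n$ to the
out-active set keeps the identity exact; the price is that degeneracy
can dip slightly below zero when detected edges point at sink nodes.

Group comparisons of network features use two-sided independent-samples
rank-sum tests on **subject-level** (full-series) connectivity matrices.
Two reasons. First, windows of one subject share the subject's coupling
graph and are not independent samples, so window-level rank tests would
overstate significance. Second, at 9 transitions per window the plug-in
bias (~0.25 bits) dominates individual entries, and the thresholded
window graphs are noise-dominated; at 149 transitions the bias is
negligible and the thresholded graph reflects the real strong coupling.
P-values are Bonferroni-corrected with family size = 3 pairs × features,
and mapped to the conventional star codes (boundaries inclusive on the
upper end: p ≤ 0.05 → `*`, ≤ 0.01 → `**`, ≤ 1e-3 → `***`, ≤ 1e-4 →
`****`). The rank-sum test is the default because the groups are
unpaired; a Welch t-test is available behind `method = "ttest"`.

## Shapley attribution

Feature attribution is model-agnostic: the value of a feature coalition
is the model's class score with the remaining features replaced by
background-set values, averaged over the background (a seeded subsample
of the training set, at most 100 rows). With at most 12 features the
Shapley values are computed by exact subset enumeration, which satisfies
local accuracy to machine precision (attributions sum to the score minus
the background base value) and the null-player axiom exactly; above 12
features a seeded permutation-sampling estimator is used (`n_perm`
random orderings per instance). Rankings order features by mean absolute
attribution, ties broken lexicographically so they are stable.

## The synthetic cohort

The generator emulates the *shape* of the imaging cohorts — three
balanced groups, 300 s of signal at TR 2 s per subject, one labeled
multichannel series per subject — with first-order linear autoregressive
network dynamics: $x_t = A\,x_{t-1} + \varepsilon_t$, Gaussian
innovations, 100 burn-in samples discarded. This is the simplest
stationary model in which directed influence is detectable by transfer
entropy. The default test scale is 20 ROIs; the 122-ROI scale of the
BASC parcellation is reachable through `n_roi` but not needed to
exercise any code path.

Group structure is planted in the coupling matrix $A$ at two levels:

* **Backbone** (shared within a group): ten strong directed edges at
  group-specific positions. TD's backbone is ten disjoint one-to-one
  edges — distributed influence with no target overlap. The ASD-like
  backbone is a single hub-out star (one hub drives ten targets):
  sparse, star-shaped, with the walker's out-weights maximally
  concentrated, hence the lowest effective information. The ADHD-like
  backbone is two five-target hub-out stars, intermediate on every
  axis. The backbone emulates the group-consistent connection
  differences on which real cohort classification rests.
* **Random edges** (subject-specific): weak directed edges at group
  densities 0.30 (TD), 0.15 (ADHD), 0.06 (ASD), with a fraction of the
  ADHD/ASD edges retargeted at hub nodes. These supply within-group
  variability and the planted density ordering.

Two design points deserve emphasis. The stars are *divergent* (hub-out)
rather than convergent (all-to-hub) because pairwise transfer entropy
cannot attribute a target driven by many simultaneous sources to any
single one of them — each source explains only a sliver of the target's
variance, and a convergent star is effectively invisible to the
estimator. A hub that solely drives each of its targets is detected
edge by edge. Second, spectral scaling of $A$ is a shrink-only cap at
radius 0.9: star and chain backbones are acyclic (spectral radius ~0),
and normalizing them *up* to 0.9 would destroy the designed weights;
capping guarantees stationarity without touching stable designs.
Innovation noise is `noise_sd = 1`; because the pipeline min-max
normalizes and binarizes each window, the dynamics are scale-invariant
and this value is a pure convention.

What the generator does **not** emulate: hemodynamic response
convolution, scanner drift and motion artifacts, site effects,
inter-regional delays beyond one sample, and the heavy-tailed,
non-stationary character of real BOLD. Passing the end-to-end tests
therefore demonstrates that the pipeline recovers planted directed
structure under its own assumptions — not that it would reach the same
numbers on ABIDE/ADHD-200.

## Numerical conventions and problem sizes

All randomness flows from explicit seeds; per-subject and per-algorithm
seeds are derived deterministically from a master seed. Refits are
bit-reproducible (probability calibration in the SVM backend and the
ARPACK eigensolvers consume the R RNG, so both run under fixed seeds).
Zero-probability terms in entropies contribute 0; ties at the binarize
threshold go to 1; zero-variance features pass through standardization
unscaled with a warning; constant features are dropped before PCA with
a warning.

The packaged analyses and tests run the full default cohort — 60
subjects, 600 window matrices, 380 features, the complete SVM grid with
10-fold CV — in a few minutes on one CPU; the module test suite uses a
smaller cohort (3 × 3 subjects, 8 ROIs) for everything that does not
need the full scale.

## Known limitations

* The binary plug-in estimator is the point of the pipeline; kernel or
  KSG estimators for continuous TE are out of scope.
* Per-window TE at 20 s / TR 2 s has ~0.25 bits of positive bias; window
  matrices are suitable as classifier features (the bias is common to
  all entries) but not as individually interpretable couplings.
* One-vs-one SVM weight aggregation in RFE is a ranking heuristic, not
  a per-class effect estimate.
* The community-scalar fallback (whole-component APL) makes inapplicable
  algorithms conservative rather than missing, which slightly compresses
  group differences in those columns.
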