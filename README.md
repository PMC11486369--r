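# teconnect

Three-class classification of resting-state brain activity (ASD / ADHD /
typically developing) from directed connectivity, with network-theoretic
interpretation.

ASD and ADHD overlap heavily in symptoms; separating the two from each
other and from typical development is a three-class problem. This
package implements the full analysis chain for doing that from ROI-level
BOLD time series:

1. **Connectivity** — each subject's series is cut into 20 s sliding
   windows; channels are min-max normalized and binarized at 0.5; every
   ordered ROI pair gets a plug-in **normalized transfer entropy**

   *TE(Y→X; τ) = Σ P(x
   <sub>t+τ</sub>, x<sub>t</sub>, y<sub>t</sub>) log₂ [ P(x<sub>t+τ</sub> |
   x<sub>t</sub>, y<sub>t</sub>) / P(x<sub>t+τ</sub> | x<sub>t</sub>) ]*,
   normalized by H(x<sub>t+τ</sub> | x<sub>t</sub>) into [0, 1],

   giving one directed, zero-diagonal connectivity matrix per window.
2. **Evaluation** — 30% stratified hold-out reserved before training
   (180 of 600 matrices), stratified shuffled 10-fold CV with in-fold
   standardization, exhaustive grid search (SVM, logistic regression,
   MLP, naive Bayes), per-class / micro / macro ROC AUC, plus
   recursive feature elimination, learning curves, additive-noise
   sweeps, k-fold stability sweeps, and chance/leakage controls.
3. **Network features** — 17 global graph measures, 7 community-reduction
   scalars (APL of the largest community under seven community-detection
   algorithms), and the **effective-information** triple
   EI = determinism − degeneracy of the random-walker dynamics on the
   thresholded directed graph.
4. **Interpretation** — model-agnostic Shapley feature attribution
   (exact for ≤ 12 features, permutation sampling above), PCA with
   feature-component correlations, and pairwise rank-sum tests with
   Bonferroni correction and star codes.

The original imaging cohorts (ABIDE, ADHD-200) require external
downloads, so the package ships a **synthetic cohort generator**:
first-order linear autoregressive network dynamics whose directed
coupling plants the group phenotypes (TD: dense, distributed strong
edges; ASD-like: sparse, star-shaped hub coupling; ADHD-like:
intermediate). Every downstream claim is tested against this planted
ground truth.

## Worked example

```r
library(teconnect)

cohort  <- make_cohort(seed = 1)                      # 3 x 20 subjects, 20 ROIs, 300 s @ TR 2 s
dataset <- build_dataset(cohort, te_config(), n_select = 600, seed = 1)
plan    <- split_plan(test_fraction = 0.30, k_folds = 10, seed = 1)
split   <- holdout_split(dataset, plan)               # 420 train / 180 test, 60 per class
fit     <- grid_search(model_spec("SVM"), split$train, plan)
evaluate(fit, split$test)
```

```
<evaluation_report> accuracy 0.983, precision 0.984, recall 0.983
  macro AUC 0.999, micro AUC 0.999; per class: ADHD 0.999, ASD 1.000, TD 0.999
```

The grid-searched SVM separates the three planted groups almost
perfectly: 177 of the 180 held-out window matrices are classified
correctly and every one-vs-rest ROC is near-perfect. A label-shuffled
control run of the same pipeline lands at CV accuracy ≈ 0.29, the
3-class chance floor.

The network-feature stage recovers the planted topology ordering on the
60 subject-level matrices:

```r
mats <- lapply(cohort, function(ts) connectivity_matrix(ts, te_config()))
ft   <- feature_table(mats, threshold = 0.5, seed = 1)
aggregate(EI ~ label, ft, mean, na.rm = TRUE)
#   label        EI
#    ADHD 1.1639859
#     ASD 0.4414238
#      TD 1.4152817
```

The ASD-like group — whose coupling is a hub-concentrated star — has the
lowest mean effective information (rank-sum ASD vs TD adjusted
p ≈ 5e-4 after Bonferroni), the ADHD-like group sits in between, and the
distributed TD coupling scores highest.

The numbered scripts under `analysis/` run the same pipeline as a
narrative workflow (simulate → connectivity → classify → network
features → interpret) and write their tables under `results/`.

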