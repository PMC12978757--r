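---
title: "Classifying wide expression matrices with hdec: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying wide expression matrices with hdec: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdec)
```

## The problem

Small expression-style studies routinely produce matrices with 40–200
samples and 200–2000 features. Distance-based and margin-based classifiers
degrade in that regime: distances concentrate, irrelevant features swamp
informative ones, and single models overfit. `hdec` implements a staged
defence: normalize, partition the samples, select features per partition,
fuse the selections, and classify with a diversified ensemble whose blocks
each see a different weighted, rotated view of the fused feature space.

The pipeline is, in order:

1. **Min-max normalization.** Each feature is mapped to
   $x \mapsto (x - \min)/(\max - \min)$ using *training-side* extrema.
2. **Deep fuzzy partitioning.** An autoencoder embeds the samples; fuzzy
   memberships, a sharpened self-training target, and a hybrid-kernel
   affinity regularizer are optimized jointly; samples are partitioned by
   their argmax membership.
3. **Hybrid recursive feature elimination.** Per partition, a linear SVM's
   squared weights are blended with a modified Fisher score and the
   lowest-ranked features are dropped iteratively.
4. **Feature fusion.** The per-partition selections are united (with
   provenance) into one fused feature set.
5. **Subspace-rotation ensemble.** Each block draws a weighted random
   subspace of the fused set, builds a rotation-forest-style PCA rotation
   on a 75% row subsample, blends the subspace with its rotated image, and
   trains one base learner (random forest, RBF SVM, or the
   weighted-Minkowski KNN); blocks vote by plurality.

## The clustering stage

For latent codes $z_x$ and centers $\beta_y$ the membership is the
fuzzified inverse of a penalized squared distance

$$D_{x,y} = \|z_x-\beta_y\|^2
  - \mu\,\frac{\sum_v \|\beta_v-\bar\beta\|^2}{\|\beta_y-\bar\beta\|^2},
\qquad
\Upsilon_{x,y} = \frac{D_{x,y}^{-1/(fuz-1)}}{\sum_v D_{x,v}^{-1/(fuz-1)}},$$

with $\bar\beta$ the mean center. The target distribution squares the
memberships, normalizes by cluster totals, and renormalizes rows; training
minimizes

$$\mathcal{L} = \frac{1}{b}\sum_x \|R(x)-x\|^2 + \gamma\|W\|^2
  + \eta_1\, KL(T\|\Upsilon)
  + \eta_2 \sum_{x,u}\|z_x-z_u\|^2\,\mathrm{Aff}_{x,u},$$

where $\mathrm{Aff}_{x,u} = \omega(z_x,z_u)^\delta$ for points sharing a
pseudo-label (argmax membership) and 0 otherwise, and
$\omega = \alpha\,e^{-r^2/2\sigma^2} + (1-\alpha)\,e^{-r/\sigma}$ is the
hybrid Gaussian/exponential kernel (positive semi-definite as a convex
combination of PSD kernels).

### Numerical choices that matter

These were settled empirically on the synthetic study conditions and are
deliberately conservative:

* **Penalty guard.** The between-cluster penalty is a *subtraction*, so at
  realistic latent scales $D$ can go negative for a third of all cells; a
  hard clamp then turns memberships one-hot and the self-training loop
  collapses every sample into one cluster. We floor each cell at half its
  unpenalized distance, $D = \max(d^2 - \mathrm{pen},\, d^2/2)$, which
  bounds the penalty's boost on any cluster's inverse-distance weight by a
  factor of 2 and keeps memberships graded. The analytic latent gradient
  accounts for the active floor (where it binds, $\partial D/\partial z$
  is halved), and the gradient test verifies this against finite
  differences.
* **Fixed penalty during the center step.** Moving a center into the
  centroid of centers inflates its own penalty without bound and is a
  degenerate descent direction for the KL term; the penalty vector is
  therefore held fixed during each center update, exactly as the target
  and affinity are held fixed during each batch step.
* **Two learning rates.** Pretraining is a single smooth objective and
  runs at $10^{-2}$ for 200 epochs; the joint phase runs at $10^{-3}$ for
  100 epochs. An under-trained latent gives the clustering nothing to
  find, while a fast joint phase lets the affinity term contract genuinely
  distinct clusters into one; the split resolves both failure modes
  (partition purity on the 3-blob reference conditions: 0.95 with the
  split vs 0.33–0.73 with a single rate).
* **Center initialization** is classical fuzzy c-means on the latent
  codes, itself started from a 10-restart k-means solution; a random-start
  fuzzy fit lands in poor local optima often enough to matter.
* **Gradient clipping.** Latent and center gradient rows are norm-clipped
  at 10; the $1/D$ factor in the membership gradient spikes when a point
  sits near a center.
* Memberships and targets are validated to sum to 1 per row within
  $10^{-10}$; the combined loss is recorded per epoch, and in full-batch
  mode with a small step ($10^{-4}$) the recorded trajectory is
  non-increasing within $10^{-9}$ — an empirical property, since the
  target and affinity are refreshed between epochs and the objective is
  not literally the same function across them.

Defaults for hyperparameters with no canonical value: fuzzifier 2,
$\mu = 0.1$, $\eta_1 = 0.1$, $\eta_2 = 0.01$, $\delta = 1$,
$\alpha = 0.5$, $\sigma$ = median pairwise latent distance resolved once
after pretraining, batch = min(256, n), latent dimension 10 over a
64-unit hidden layer with tanh activations. All are configurable in
`idfc_config()`.

Partitions must contain at least 2 samples of every class so that each
partition can train its own margin classifier; violating partitions are
merged into the partition with the nearest center until the invariant
holds.

## Feature scoring and elimination

The classical Fisher score weights class deviations by class size $n_d$
against pooled within-class variance:

$$s(f_a) = \frac{\sum_d n_d\,(\mu_{da}-\mu_a)^2}
                {\sum_d n_d\,\sigma^2_{da}}.$$

The modified variant studentizes the global mean,
$\phi(\bar f_a) = (\bar f_a - \mu_0)/SE(\bar f_a)$ with $\mu_0$ the grand
mean of the matrix and $SE = sd/\sqrt{n}$, and scores

$$Ms(f_a) = \frac{\sum_d n_d\,(\mu_{da}-\phi(\bar f_a))^2}
                 {\sum_d n_d\, SE(\bar f_a)}.$$

Two interpretive choices are implemented literally and flagged: the class
weight is the class sample count (a mean *vector* cannot weight a scalar
sum), and the denominator uses the standard error as written even though
it is dimensionally unusual — `modified_fisher_score(...,
variant = "classic-denominator")` substitutes the pooled-variance
denominator for sensitivity analyses. Within-class variances use the
population (1/n) form. The elimination rank blends the max-normalized
squared weights of a linear SVM (refit every iteration, the standard
recursive-elimination protocol) with the max-normalized modified Fisher
score at $\alpha_{rank} = 0.5$; `alpha_rank = 1` recovers conventional
SVM-RFE and is the selection-ablation variant. Each iteration drops the
lowest-ranked 10% (ceiling, never below the target size; exact rank ties,
including ties up to float noise from the margin fit, drop the higher
original index first). The stopping size (50 per partition) and drop
schedule have no canonical values; both are configurable and logged in
the elimination trace. Fusion is the deduplicated sorted union of
original indices with a provenance map — the minimal
information-preserving reading of "combine the selected sets".

## The ensemble

With fused set $F_f$ and ratio $\gamma$, each block draws
$M = \max(2, \mathrm{round}(\gamma\,|F_f|))$ primary indices and an
independent secondary draw of the same size, assigns uniform weights
$W \sim U(0.5, 1.5)$, and multiplies weights by $1+\lambda$ on columns
present in both draws. The set-algebraic overlap term has no defined
algebra as a sum, so it is realized multiplicatively — overlap *emphasis*
rather than addition — keeping the subspace dimension at $M$;
$\lambda = 0.3$ by default. The rotation partitions the $M$ columns into
random disjoint groups whose size is drawn per block from $\{2,3,4\}$
(the "multi-scale" element), fits a full-component PCA per group on a 75%
row subsample (without replacement, the rotation-forest convention; a
with-replacement mode exists behind `bootstrap_replace`), and assembles
the loadings into an orthogonal $M \times M$ matrix checked to $10^{-6}$.
The enhanced matrix is $\varepsilon = \alpha S + (1-\alpha)SR$; a
QR-orthogonalized Gaussian rotation is available via
`mse_rotation = "random"` for comparison. Blocks train, in order, a
random forest, an RBF SVM, and the weighted-Minkowski KNN (cycling for
more blocks), each on all training samples — the partitions serve feature
selection only. Prediction is plurality voting; ties fall back to summed
per-class scores where learners expose them, then the lowest class index
(binary tasks with three voters cannot tie). Vote fractions double as ROC
scores, taking values in $\{0, 1/3, 2/3, 1\}$ for the default ensemble.

## The weighted-Minkowski KNN

The value parameter of feature $i$ is
$\nu_{p,i} = 1 - (acc_0(i) - acc_e)$, where $acc_e$ is the 3-fold
stratified cross-validated accuracy of a conventional Euclidean KNN
averaged over $k \in \{3,5,7\}$ and $acc_0(i)$ the same with feature $i$
removed (leave-one-*feature*-out; cross-validation rather than
resubstitution is a choice, as no estimation protocol is canonical).
Weights $W_i = \nu_{p,i}/\sum_j \nu_{p,j}$ enter
$d(a,b) = [\sum_i W_i\,|a_i-b_i|^\rho]^{1/\rho}$ with $\rho = 2$ by
default; with uniform weights this is Euclidean distance scaled by
$1/\sqrt{t}$, so neighbour sets coincide with the conventional rule —
the tested "conventional KNN" limit. Prediction averages the
weighted-Minkowski distances of the $k = 5$ nearest neighbours per
represented class and picks the smallest average (ties: larger neighbour
count, then lower class index); averaging over *all* training points per
class is kept as `scope = "all"` since the per-class averaging rule is
ambiguous between the two readings. $\nu_p$ is clamped at $10^{-6}$ so
weights stay positive. The $O(t)$ leave-one-feature-out loop reuses one
squared-distance matrix and subtracts each feature's contribution, so it
is cheap at post-fusion dimensionalities.

## Evaluation harness

`run_experiment()` runs, per seed, a stratified 80:20 split, an optional
inner 5-fold cross-validated grid search on the training side, a final
fit, and test-side metrics: accuracy, sensitivity, specificity,
precision, F-measure, MCC, NPV, FPR, FNR, and trapezoidal AUC (equal to
pairwise concordance with ties counted ½). Zero-denominator ratios are
reported as 0 and flagged rather than raised — test sides with a handful
of samples routinely produce empty confusion cells. Multiclass tasks are
scored one-vs-rest per class with macro averages; accuracy stays plain.
The inner grid search defaults to *off* (`grid = NULL`): the tuning loop
multiplies the pipeline cost by the grid size times the fold count, and
the package's defaults are themselves the reference conditions;
`default_grid()` supplies the $\gamma \times \alpha_{mse}$ grid when
tuning is wanted. `sensitivity_sweep()` varies $\gamma$ and, by default,
the hybrid-kernel mixing weight (the clustering stage is refit per alpha
and shared across $\gamma$ cells, which only affect the ensemble);
`which_alpha = "mse"` sweeps the mixing coefficient instead.
`ablation()` pairs three variants on identical splits: the full pipeline,
single-Gaussian-kernel clustering (`alpha_kernel = 1`), and margin-only
elimination (`alpha_rank = 1`).

The harness never touches test rows before the final evaluation:
normalization parameters are fitted on the training side by default. The
order used by many small-benchmark studies — normalize first, split
second — is available as `normalize_before_split = TRUE` and documented
as leakage-prone.

## What the synthetic generator does and does not emulate

`generate_classification()` plants a configurable number of informative
features carrying a between-class mean shift of `effect_size` noise
units, optional equicorrelation among them, and an independent latent
blob structure embedded across all features through a random linear map
(unit-norm columns, so separation stays in noise units). The reference
conditions are n = 200, d = 500, 30 informative features at effect 1.5,
two balanced classes, three latent blobs at separation 6 — inside the
dimensionality regime of the small expression benchmarks this package
targets while staying desk-scale. Separation 6 was chosen so that the
advertised latent structure survives normalization and is actually
discoverable at d = 500; at 4 the pretrained embedding still resolves the
blobs but the joint clustering phase erases them. The generator does not
model platform noise, probe effects, batch structure, heavy-tailed
intensities, or class-correlated cluster structure, so passing tests
demonstrate algorithmic correctness and sane behaviour at realistic
shapes — not performance on real microarray data.

Problem sizes used by the test suite: formula oracles run on matrices of
at most 20 × 5; recovery simulations use n = 120, d = 100 (selection),
n = 150, d = 50 (clustering), and n = 100, d = 5 (KNN weighting); the
end-to-end benchmark runs the full reference conditions over 10 seeds,
the ablation over 10, and the sensitivity sweep over 2.

## Known limitations

* The clustering stage inherits the fragility of self-training: with weak
  or absent latent structure it can still merge genuinely distinct groups
  (the partition fallback keeps the pipeline well-posed either way).
* The balance penalty is stabilized by a guard that modifies the formula
  wherever the penalty would exceed half the squared distance; at large
  $\mu$ the implemented membership is therefore deliberately not the
  literal (divergent) expression.
* Accuracy at small subspace ratios ($\gamma = 0.2$) genuinely drops a
  few points on the reference conditions — with ~110 fused features a
  20% draw leaves each block ~22 columns, few of them informative; the
  sweep's reported spread reflects that plus small-test-set noise
  (40 test samples).
* The execution backend abstracts the master/worker topology as a
  deterministic parallel map over partitions; a genuine cluster adapter
  is a documented extension point, not shipped.
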