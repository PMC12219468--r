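---
title: "Quantifying universal and brain-shared representational dimensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying universal and brain-shared representational dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unidim)
```

## The problem

When many neural networks are trained — or many brains perceive — the same
stimuli, some representational dimensions recur in every system while others
are idiosyncratic accidents of initialization, architecture, or task. This
package quantifies that distinction for every latent dimension of a network
and relates it to brain data through two per-dimension statistics:

* **Universality** of dimension $d$: the *median*, over the other $m$
  networks in a set, of the cross-validated accuracy $r_{d,i}$ with which
  network $i$'s activations predict $d$,
  $\mathrm{Universality}_d = \mathrm{median}(r_{d,1},\dots,r_{d,m})$.
  The median keeps the summary from being driven by a few predictors with
  exceptionally high or low scores.
* **Brain similarity** of $d$: the *mean*, over $n$ subjects, of the
  cross-validated accuracy with which each subject's voxel responses predict
  $d$, $\mathrm{BrainSimilarity}_d = \mathrm{mean}(r_{d,1},\dots,r_{d,n})$.

Dimensions are the principal components (PCs) of a layer's spatially pooled
activations, so each target is drawn from an orthogonal basis rather than
from redundant channels. The downstream questions — are the two metrics
coupled, does the coupling survive controlling for PC rank, is it absent
when it should be absent, and do the top universal dimensions carry a
network's representational geometry — are answered by rank correlations,
an image-label permutation test, and representational similarity analysis
(RSA) with universal-subspace reduction.

## The generative model behind the synthetic worlds

Real activations and fMRI data are large and external; the package instead
ships a latent-factor world generator whose statistical structure matches
what the analysis assumes, so every claim can be tested against planted
ground truth.

For stimulus $s$, network $i$, layer $l$:

$$
A^{(i,l)}_{s\cdot} \;=\; z^{\mathrm{shared}}_{s\cdot} W^{(i,l)}_{\mathrm{sh}}
 \;+\; z^{(i)}_{s\cdot} W^{(i,l)}_{\mathrm{id}} \;+\; \varepsilon,
$$

with all latents and loadings iid normal. `universal_scale` (default 1) and
`idio_scale` (default 0.3) are the loading standard deviations; because the
shared scale dominates, shared structure occupies the top of every layer's
variance spectrum, which is the qualitative situation the analysis is
designed to detect. Subjects see the same stimuli through
$V^{(j)} = Z_{\mathrm{brain}} B^{(j)} + \varepsilon_j$, column-standardized
per voxel to emulate session z-scoring. `brain_latents` selects the regime:
`"all"`/`"subset:k"` couple the brain to (some of) the shared latents (the
*aligned world*); `"disjoint"` samples brain latents independently (the
*null world*), in which universality still spans its full range while brain
similarity carries no information about it.

Choices worth knowing about:

* **`n_spatial = 1` by default.** With more than one spatial position,
  global max pooling of linear mixtures is a nonlinearity, and the
  generator's ground-truth variance decomposition
  (`shared_variance_fraction()`, the quadratic form
  $v^\top W_{\mathrm{sh}}^\top W_{\mathrm{sh}} v / v^\top \Sigma v$ for a PC
  loading $v$) is exact only in the linear case. The default keeps the
  planted-recovery oracle exact; `n_spatial > 1` and `nonneg = TRUE` are
  available to probe pooling and rectification regimes.
* **Rectification off by default**, so recoverability is linear; turning it
  on probes the ReLU-distorted regime.
* **Fit/evaluation stimuli are generated jointly and split by index** (fit
  first), mirroring a design with a large unshared fitting set and a
  smaller shared evaluation set.
* Default problem sizes (600 fit / 200 evaluation stimuli, 6 networks ×
  3 layers × 60 channels, 3 universal + 6 idiosyncratic latents, 4 subjects,
  120 voxels, noise SD 0.1) are the package's reference study conditions:
  large enough that 1,080 dimensions are scored and the planted structure is
  identifiable, small enough to run on a laptop core in seconds.

What the generator deliberately does *not* emulate: image content, actual
DNN forward passes, fMRI noise structure beyond additive Gaussian noise plus
standardization, inter-subject anatomical variability, or heavy-tailed
eigenspectra of real networks. Passing tests on these worlds therefore
demonstrate correctness of the estimation machinery and the qualitative
behavior of the metrics — not that any particular real network is universal.

## Feature extraction

Layers are reduced to stimuli × channels matrices by global max pooling over
the spatial axis. PCA is fitted on the *fit* split only, centering by
fit-set channel means (the evaluation set is projected with those means and
is never re-centered on its own statistics — no peeking). All components up
to the numerical matrix rank are retained, with the conventional tolerance
(largest dimension × machine epsilon × top singular value). Channels are not
variance-standardized before PCA. The PCA transformation is applied to
target features only; predictor networks enter as raw pooled activations
concatenated across layers, so each predictor contributes a single
regression per target dimension.

## The mapping engine

Every $r_{d,i}$ is a nested cross-validated ridge regression:

* **Outer loop**: 5 folds over the evaluation stimuli, assigned by a
  uniformly random permutation with a recorded seed (sizes differ by at
  most 1).
* **Inner loop**: on each training set of 4 folds, leave-one-out (LOO)
  cross-validation selects the ridge penalty per target among $\{0\}$ and
  eight log-spaced values $10^{-3},\dots,10^{4}$. The selection criterion is
  the LOO Pearson correlation (matching the outer metric); minimizing LOO
  MSE is available as a switch.
* Weights are refitted on the full training folds at the selected penalty,
  and the fold's score is the Pearson correlation between predicted and
  actual responses on the held-out fold; `mean_r` averages the five folds.

Numerical design:

* LOO residuals use the closed-form hat-matrix identity
  $e_i = (y_i - \hat y_i)/(1 - h_i)$, with $h_i$ including the unpenalized
  intercept's $1/n$ term; this equals explicit refitting to machine
  precision and is what makes the permutation test affordable.
* $\lambda = 0$ is the minimum-norm least-squares solution when the design
  is rank-deficient. On an *interpolating* training matrix (column-centered
  rank $n-1$), the hat identity degenerates ($h_i \to 1$); there the
  ridgeless kernel limit $e_i = [K^{-1}y]_i / [K^{-1}]_{ii}$ with
  $K = X_c X_c^\top$ is used, which the test suite verifies against explicit
  minimum-norm refits.
* Degenerate predictions (zero variance on a fold, e.g. total shrinkage)
  score $r = 0$, never `NaN`; degenerate targets select the smallest grid
  value and are flagged.
* One engine per predictor matrix caches the per-fold SVDs; they depend
  only on predictors and the fold plan, so all ~1,000 target dimensions and
  all permutation iterations reuse them. Scoring all dimensions of the
  reference world takes a few seconds; one permutation iteration ≈ 2 s on
  one core.

Alternative mapping methods share the outer folds: OLS is the engine with
the penalty pinned to 0 and no inner loop; one-to-one mapping picks, per
fold, the training column with the highest *signed* Pearson correlation with
the target and scores that single column on the held-out fold (constant
columns excluded; a fold with no usable column scores 0).

## Inference

The association between universality and brain similarity is summarized by
a Spearman correlation (Pearson on midranks) and a partial Spearman
controlling for PC rank (midrank-transform all three variables, residualize
the ranked metrics on the ranked control by least squares, correlate the
residuals). Significance comes from an image-label permutation test: each
iteration draws one permutation of evaluation-stimulus indices per target
network and applies it to *all* of that network's dimensions — preserving
within-network feature dependence — then recomputes every universality score
and the Spearman correlation against the *unpermuted* brain similarities.
The one-sided p-value is add-one corrected,
$p = (1 + \#\{\rho_{\mathrm{null}} \ge \rho_{\mathrm{obs}}\})/(n_{\mathrm{perm}}+1)$,
so it is never 0 and never below $1/(n_{\mathrm{perm}}+1)$; `n_perm < 19` is
refused because the floor would exceed 0.05. The test is one-sided because
the scientific claim under test is a positive association. The desk-scale
default is `n_perm = 199` (p floor 0.005); 5,000 is the full-scale
convention and is a config switch.

## Reliability

`between_subject_reliability()` estimates a noise ceiling per dimension: the
mean over subject pairs of the Pearson correlation between their
cross-validated predicted series for that dimension, clamped to $[0,1]$. A
dimension's brain similarity can only be as high as the consistency of the
brain data predicting it. The adjustment divides by
$\sqrt{\mathrm{reliability}}$ (the attenuation-correction convention;
dividing by the raw reliability is a switch), and dimensions below a
reliability floor (default 0.1) are excluded rather than divided, because
the correction explodes there. The exact reliability formula is a design
choice of this package; the prediction-consistency form was chosen because
it directly upper-bounds the attainable brain similarity.

## RSA with universal-subspace reduction

Evaluation stimuli are split into random train/test halves (an odd stimulus
goes to train). Representational dissimilarity matrices (RDMs) are Pearson
correlation distances ($1-r$; zero-variance conditions get distance 1,
flagged), compared by Spearman correlation over the strictly lower
triangle. Per network, the layer whose train-half RDM best matches the
subjects' train-half RDMs (averaged after per-subject Spearman) is selected
— ties to the shallower layer — and the reported similarity uses the
held-out test half. The reduced analysis reconstructs the selected layer's
test-half activations from only its $k$ most universal dimensions
(`reconstruct_topk()`), default $k \in \{10, 5\}$, and recomputes the test
similarity. Ranking is within the selected layer by default; ranking across
the whole network (keeping the selected layer's members of the network-wide
top $k$) is available behind `scope = "network"` — which of the two a study
should prefer is genuinely open, and the layer-local form was chosen because
RDMs are computed per layer. $k$ above the layer rank is clamped and
flagged.

## What the reference worlds show (and don't)

On the aligned reference world, the planted shared PCs (ground-truth shared
variance ≥ 90%) are recovered with universality above 0.97 and dominate
brain similarity in every paired comparison with idiosyncratic PCs; the
universality/brain-similarity Spearman is strongly positive, survives
controlling for PC rank, and beats all 199 permutation draws. On null
worlds the correlation sits within ±0.05 of zero while universality still
spans more than its full interquartile structure, and repeated end-to-end
p-values are consistent with uniformity — the test is calibrated. These
statements are exactly what the test suite and `scripts/acceptance.R`
recompute; no further empirical claims are made.

Two caveats surfaced by the planted-truth analysis are worth knowing:

* The idiosyncratic/noise bulk of dimensions carries small shared-variance
  leakage (PCA does not isolate the shared subspace perfectly), so its
  universality *tail* reaches ≈ 0.2–0.3 even though its central mass sits
  near 0. Thresholded claims about "all low-shared dimensions" are
  order-statistics over ~1,000 noisy estimates and should be phrased in
  quantiles, as the tests here do.
* Cross-method rank agreement (ridge vs. OLS vs. one-to-one) is high among
  dimensions that carry signal, but over the zero-signal bulk it reflects
  only estimation noise; with concatenated predictors near the
  interpolation threshold ($p \approx n$), unregularized OLS is especially
  unstable. Whole-table rank correlations between methods are therefore
  moderate on these bimodal synthetic worlds, unlike on real networks whose
  universality is a continuum.

## Problem sizes and runtime

The reference configuration (1,080 dimensions, 5 predictors + 4 subjects
per dimension, 199 permutations) runs end to end in roughly ten minutes on
one core; the calibration experiment uses a reduced world (3 networks ×
1 layer × 12 channels, 60 evaluation stimuli, 99 permutations, 50
repetitions). These sizes were chosen so that every planted effect is
detectable with margin while the whole suite stays interactive.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(world = world_config(), n_perm = 199, seed = 1)
res <- run_all(cfg)
res$summary$rho          # Spearman(universality, brain similarity)
res$summary$rho_partial  # after controlling for PC rank
res$summary$p_value      # image-label permutation test
head(res$quantiles)      # quantile-bin trend curve
res$rsa$network1$test_similarity_reduced  # top-10 / top-5 RSA
```

## Known limitations

* Synthetic worlds are linear-Gaussian by default; claims about strongly
  nonlinear recoverability require `nonneg = TRUE`/`n_spatial > 1` variants
  and were not the focus of the reference conditions.
* The reliability metric is one defensible choice among several; switching
  conventions changes adjusted values but not, on the reference worlds, the
  qualitative trend. One behavior to be aware of: when subjects are
  near-noiseless copies of the same low-rank response space, their
  cross-validated predictions of *any* target collapse onto the same
  projection, so prediction-consistency reliability can be high even for
  unpredictable dimensions — it bounds consistency, not predictability.
  With realistic per-subject noise the two coincide.
* Permutation inference treats dimensions as the units of the rank
  correlation; dependence among dimensions of one network is respected by
  the shuffling scheme, but dependence across networks that share latents
  is not modeled in the null.
* The CSV/JSON persistence layout is meant for moderate matrix sizes; very
  large activation sets would warrant a binary container.
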