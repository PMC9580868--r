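---
title: "Accelerated voxel annotation: model, feature bank and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated voxel annotation: model, feature bank and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelearn)
```

## The problem

Expert annotation of 3D image stacks — tumors in CT/MRI, dendritic arbors
in confocal microscopy — is slow because exhaustive voxel-by-voxel
labeling does not scale. `voxelearn` implements a one-shot,
human-in-the-loop alternative: the user sweeps a handful of labeled
strokes through the volume (positive strokes inside the structure of
interest, large negative streaks through the background), a classifier is
trained on the few hundred voxels those strokes touch, and the trained
model classifies *every* voxel of the stack, producing a probability map
that is overlaid on the raw data for inspection and, if needed, corrected
with another round of strokes.

The package is deliberately headless: strokes are polylines with a brush
radius, so the same pipeline can be driven from scripts, from the bundled
command-line tool, or from any interactive front end that can emit
polylines.

## The model

For voxel $v$ with feature vector $x_v \in \mathbb{R}^{56}$ and sparse
labels $y \in \{0, 1\}$ (1 = structure of interest), a base classifier
$f$ is fit on the tagged voxels and the whole volume is scored with
$p_v = f(x_v) \in [0, 1]$, the probability that $v$ belongs to the
positive class. Five base classifiers are provided, all standard choices
for small-sample tabular learning: random forest (RFC), a single-hidden-
layer perceptron (MLP), gradient boosting (XGB), an RBF support vector
machine with probability outputs (SVM), and Gaussian naive Bayes (NBC).

The *strong learner* is a stacked ensemble: the four weak learners
{RFC, MLP, SVM, NBC} are trained first, their predicted positive-class
probabilities on the training voxels are appended to the feature matrix
(56 + 4 = 60 columns), and a gradient-boosting meta classifier is trained
on the augmented matrix. At inference the weak probabilities are computed
for every voxel and fed to the meta model the same way. By default the
appended probabilities are in-sample predictions: the purpose of one-shot
annotation is to annotate the volume being explored, not to build a
generalizing model, so out-of-fold stacking (available via
`train_strong(out_of_fold = TRUE)`) is not the default. The strong
learner tends to commit harder than RFC — its probability histogram is
more bimodal, with fewer voxels left in the ambiguous mid-range — at the
price of slightly more false negatives, which matches its design intent
of being a stricter annotator.

## The 56-feature bank

Each voxel is described by the raw intensity (`PIXEL_VALUE`, feature 0)
plus 11 filter kinds × 5 kernel sizes $k \in \{3, 5, 7, 9, 11\}$ voxels:

| group | filters |
|---|---|
| smoothing | Gaussian, mean, median |
| order statistics | minimum, maximum, range |
| texture | standard deviation |
| differential geometry | gradient magnitude, Laplacian of Gaussian, difference of Gaussians, largest Hessian eigenvalue |

Choices a reader should know:

* **Gaussian scale.** $\sigma = k/6$, so $\pm 3\sigma$ spans the kernel;
  the kernel is truncated to length $k$ and renormalized. The difference
  of Gaussians subtracts the response at $2\sigma$, truncated to the same
  kernel.
* **Derivatives.** Gradient, Laplacian and Hessian entries are central
  finite differences of the Gaussian-smoothed volume at unit voxel
  spacing. The Hessian feature is the largest (signed) eigenvalue of the
  $3 \times 3$ Hessian, computed in closed form; it responds strongly to
  thin tubular structures, which is why it earns a place in a bank meant
  to cover both bulky and filamentous objects.
* **Borders.** All filters use symmetric (edge-included) mirror padding.
  Zero padding would manufacture spurious edges exactly where users tag
  near volume faces.
* **Units.** Features are computed in 64-bit reals on the native
  intensity scale, with no normalization: tree ensembles are scale-free,
  and keeping `PIXEL_VALUE` in native units makes importance reports
  directly interpretable. The MLP standardizes its inputs internally (it
  is not scale-free); the SVM relies on its own internal scaling.
* **Isotropy.** Kernels are isotropic 3D; anisotropic voxel spacing is
  recorded on the volume but not folded into the filters.

Sparse per-voxel evaluation (`compute_features_at()`, used at training
time) replicates the dense separable-pass arithmetic of
`compute_features_full()` operation-for-operation, so the two paths agree
bit-for-bit — the tests assert equality rather than closeness. Dense
computation can be tiled (`block_shape`) with a mirror-padded halo of
kernel radius + 2 voxels (the +2 covers the finite-difference stencils
chained after smoothing); tiling is a pure memory knob and does not
change results.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| stroke `radius` | 1 voxel | brush radius swept along the polyline |
| RFC `ntree` | 100 | trees; `nodesize = 1` (fully grown) |
| XGB `nrounds`, `max_depth`, `eta` | 100, 3, 0.1 | boosting rounds, tree depth, learning rate |
| MLP `size`, `maxit`, `decay` | 32, 200, 1e-4 | hidden units, epochs, weight decay |
| SVM `cost` | 1 | RBF misclassification cost (`gamma`: 1 / n features) |
| threshold | 0.5 | probability cut for masks; ties count positive |
| log floor | 1e-12 | `log_transform()` floors probabilities here |

The MLP default (one hidden layer of 32 units, 200 epochs) was chosen so
that a few-hundred-tag training set fits in seconds under `nnet`'s BFGS
optimizer while still being grossly over-parameterized for the task; all
hyperparameters can be overridden per call.

## Evaluation conventions

`dice()` thresholds the probability map (default 0.5, ties positive) and
computes $2\,\mathrm{TP} / (2\,\mathrm{TP} + \mathrm{FP} + \mathrm{FN})$;
two empty masks score 1 by convention. `rmse()` is computed on the raw
probabilities against the binary reference over *all* voxels of the
volume, with no region-of-interest restriction — so it rewards confident,
correct probabilities, not just correct masks.

## The synthetic phantoms

The generator emulates the two structure classes the pipeline targets:

* `blob` — bulky, tumor-like: unions of ellipsoids (default one centered
  ellipsoid with radii ≈ 28% of the volume side).
* `tubes` — thin, neurite-like: random walks with momentum
  (persistence 0.9) swept to a tube radius, reflected off the volume
  faces. The momentum walk produces dendrite-like curvature without
  needing a morphology library.

Object and background intensities default to 200 and 10; noise is
Gaussian (default) or Poisson. The standard fixture suite used by the
tests and the acceptance script is pinned: `blob_clean` (32³, no noise),
`blob_noisy` (32³, Gaussian noise with sd = 20% of the contrast, i.e. 38)
and `tubes_noisy` (48³, 3 tubes of radius 1.5, same relative noise).
These sizes keep a full train-plus-dense-inference cycle in the tens of
seconds on one core while leaving the noisy fixtures genuinely hard at
the voxel level (voxelwise two-sigma overlap between classes).

`simulate_strokes()` emulates the user: positive strokes are short random
walks constrained inside the object; negative strokes are long straight
streaks anchored to pass the object, clipped to the background — the way
a user rapidly swipes past a structure to tag its surroundings. All
returned tags are label-consistent with the ground truth by construction.
What the phantoms do *not* emulate: intensity inhomogeneity, anisotropic
point-spread functions, partial-volume boundary voxels, imaging
artifacts, or ambiguous anatomy. Passing the phantom suite therefore
demonstrates that the machinery is correct and that recovery works under
honest noise, not that any particular clinical Dice level will be
reached.

The correction-round fixture deserves a note: with balanced 2+2-stroke
tagging the first round's residual error on `blob_noisy` is entirely
false *negatives*, leaving nothing for a false-positive-erasing second
round to fix. The frozen correction scenario therefore uses unbalanced
tagging (5 positive strokes, 1 background streak), which under-samples
the background and leaves tens of false detections — precisely the
pathology iterative re-tagging exists to correct; the second round then
raises Dice.

## The job service

Training and inference can be routed through a directory-backed job
service that mirrors a remote-learning REST API: create job → upload
inputs → launch → poll status (`created → running → done | error`) →
list outputs → download. Workers run asynchronously in separate R
processes; feature payloads are serialized with 17 significant digits, so
remote training is bit-identical to a local run with the same seed. The
`created` state (not part of the running/done/error trio) makes
"uploads before launch" well-defined. The service is embeddable rather
than socket-bound: `svc_handle_request()` exposes the six endpoints as a
method + path + body dispatcher, which is the whole REST surface minus
the transport.

## Numerical and degenerate-input choices

* Stroke voxelization is *exact*: a voxel is tagged iff its center lies
  within the brush radius of the polyline (point-to-segment distance over
  per-segment bounding boxes). An earlier sampled-ball discretization was
  discarded because it can miss voxels by up to a quarter voxel and
  cannot match a brute-force oracle.
* Re-tagging the same voxel with both labels in one round is a validation
  error; across rounds, the newest event wins, and erasures are kept as
  events so the audit trail of corrections survives.
* Naive Bayes per-feature standard deviations are floored at $10^{-6}$ of
  the overall feature scale so constant features (common on clean
  phantoms) keep finite densities.
* Single-class training sets, NaN features, schema mismatches between a
  model and a feature matrix, and out-of-bounds voxel IDs all fail fast
  with validation errors rather than propagating.
* On a constant volume every smoother returns the constant and every
  differential feature returns 0 up to floating-point cancellation
  (≈ 1e-7 for the standard deviation, whose square root amplifies
  cancellation error).

## Known limitations

* Binary labels only (positive/negative), matching the annotation task;
  no multi-class support.
* Isotropic filters; strongly anisotropic acquisitions should be
  resampled first.
* The probability colormap interpolates linearly from blue (0) through
  magenta to red (1); this is a rendering convention, not a calibration
  statement.
* The MLP and SVM are the slowest links at inference time on large
  volumes; RFC is the recommended default, which is also where the
  impurity-based importance report comes from.
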