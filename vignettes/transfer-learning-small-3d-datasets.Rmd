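---
title: "Autoencoder transfer learning for small 3D image datasets: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoencoder transfer learning for small 3D image datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phantomnet implements a complete pipeline for binary classification of small
3D grayscale medical-image datasets — the regime where a clinic can supply a
few dozen labeled volumes, far too few for ordinary deep learning. The
pipeline couples five stages: synthetic phantom generation (so everything is
testable without data downloads), intensity preprocessing, rigid
augmentation, patch-based convolutional autoencoder pretraining on a
separate unlabeled corpus, and a small 3D CNN classifier whose convolutions
are initialized from the pretrained encoder. Evaluation follows the
protocol a practitioner would use at this sample size: leave-one-out
cross-validation (LOOCV), repeated hyperparameter grid search,
confidence-ranked triage curves, and paired comparisons of transfer versus
random initialization.

This vignette explains the models, their assumptions, and the numerical
design choices — including where the design was genuinely open and what we
chose.

## The synthetic volumes

Real volumes of this kind are T2-weighted MR images: grayscale, noisy, with
an anatomical region (the head) on a dark background and, in unhealthy
subjects, a hyperintense lesion. `make_phantom()` emulates the minimum
structure that makes every downstream stage meaningful:

* an ellipsoidal **tissue** region (semi-axes 45% of each volume dimension)
  of uniform intensity on a dark background;
* optionally one spherical **lesion core** of radius drawn uniformly from
  `lesion_radius_range`, with intensity `tissue_level + lesion_contrast`
  exactly;
* a **peritumoral edema halo** out to twice the core radius, confined to
  tissue, decaying linearly from `edema_fraction * lesion_contrast` at the
  core edge to zero. T2-weighted tumor presentations are dominated by
  exactly this kind of graded hyperintense surround; numerically it matters
  because it makes the lesion footprint several times the core volume, so a
  lesion is a spatially extended pattern rather than a handful of voxels;
* **Rician magnitude noise**: each voxel becomes
  `sqrt((v + n1)^2 + n2^2)` with independent zero-mean Gaussians `n1, n2`
  of standard deviation `noise_sigma`. This is the exact law of
  magnitude-reconstructed MR images; it reduces to Rayleigh noise (mean
  `sigma * sqrt(pi/2)`) at zero signal and to additive Gaussian noise at
  high SNR, and both limits are asserted in the test suite against
  closed forms.

Lesion centers are drawn from the tissue ellipsoid shrunk by
`lesion_center_fraction` (default 0.5). This was a genuinely open choice:
with unrestricted centers, the class signal at desk-scale sample sizes is
almost perfectly position-coded — a small bright blob anywhere in the
tissue — and a flatten-plus-dense readout trained on a dozen examples
cannot generalize across unseen positions (its linear span covers only the
training positions). Centrally placed lesions keep held-out lesion
positions inside the orbit that rigid augmentation and the small training
set can cover, which is also a fair miniature of registered clinical data,
where the anatomy (and the plausible tumor sites) are far more aligned
across subjects than "uniformly anywhere".

The unlabeled source corpus (`generate_source_corpus()`) models the
pretraining database: same noise model and anatomy, but a stated
distribution shift — 50% lesion prevalence and a wider lesion radius range.
Tests assert the shift is visible (corpus mean intensity differs from an
all-healthy target set).

What the generator deliberately does **not** model: realistic brain
anatomy, bias fields, multi-sequence contrast, scanner-dependent artifacts,
or anatomical variability between subjects. Passing tests on phantoms
therefore demonstrate that the pipeline's machinery — preprocessing,
augmentation geometry, weight transfer, evaluation protocol — behaves as
specified, not that the classifier would reach any particular accuracy on
clinical data.

## Preprocessing

Volumes arrive as stacks of 2D slices (`stack_slices()`), and are made
comparable in two steps, mirroring display-window practice in radiology:

1. **Intensity windowing** (`compute_window()` / `apply_window()`): the
   window `[lower, upper]` covers the central 95% of the voxel-intensity
   distribution (coverage configurable). "Cover 95%" admits several
   readings; we take symmetric central quantiles — trimming 2.5% at each
   tail — which is the standard display-window interpretation. Quantile
   indices are interpolation positions snapped *outward* to the bracketing
   order statistics, which guarantees the realized coverage is at least the
   requested coverage on every input (asserted over random fixtures).
   Out-of-window voxels are clipped, then the window is rescaled linearly
   to [0, 1]; clipping preserves shape and is standard practice. Windows
   are computed per image.
2. **Brightness normalization** (`fit_normalizer()` /
   `apply_normalizer()`): `(v - train_mean) / (train_max - train_min)`
   with mean/min/max pooled over *training-set* voxels only, applied
   identically to training and held-out volumes. The formula beyond "mean"
   and "range" was an open choice; this one centers the training set at
   exactly zero pooled mean (asserted to 1e-10). Fitting on the training
   fold only is a hard requirement — the leakage guard is tested by
   recomputation with and without held-out samples.

## Rigid augmentation

Each labeled volume is expanded with `k` random label-preserving rigid
perturbations (default `k = 14`): an in-plane rotation about the slice
center into enlarged bounds recomputed from the rotation matrix
(`new_h = ceil(h|cos| + w|sin|)`, `new_w = ceil(h|sin| + w|cos|)`), then a
translation — composed into a single affine so each voxel is interpolated
once. All slices of a volume share the transform; rotation is in-plane
because the geometry is described in 2D rotation-matrix terms and coronal
stacks have coarse depth resolution. Magnitude ranges are configuration
knobs (`max_angle` 25 degrees, `max_shift_fraction` 0.1) since no canonical
values exist. Interpolation is bilinear for intensity images (nearest
available), with fill value 0 — the background level after windowing.

Numerical notes: bilinear resampling conserves the total intensity of an
interior delta image exactly (partition of unity) for pure translations,
but only approximately for generic rotations, where the resampled hat
functions no longer tile; the tests assert 1e-6 for translations and a
coarse band for rotations. Quarter turns with nearest-neighbor sampling are
exactly invertible and are tested as such.

## Patch autoencoder and weight transfer

Pretraining follows the patch regime: 25 x 25 x 4 voxel patches sampled
uniformly with replacement (20000 per volume at full scale; benchmark
configurations subsample). The autoencoder is a stack of 1–3 convolutional
encoder layers (3x3x3 kernels, stride 1, zero "same" padding, ReLU) with a
mirrored decoder whose final layer is linear, trained to minimize
mean-squared reconstruction error with Adam (1e-3, 20 epochs, batch 128 by
default). Stride-1 same-padding convolutions keep every shape compatible
with the classifier grid; no pooling is used anywhere. Depth and filter
counts default to (16, 32, 64), mirroring the classifier grid so transfer
shapes match exactly.

`initialize_from_encoder()` copies encoder layer i into classifier
convolution i, in order, for as many layers as both share; on a
filter-count mismatch the leading sub-tensor is copied and the remainder
keeps its random initialization. Fully connected layers are untouched, and
all layers remain trainable (no freezing) — fine-tuning everything is the
simplest reading of "trained in the same way", and the prefix-copy contract
is asserted bitwise.

Source-side preprocessing mirrors the target pipeline: corpus volumes are
windowed per image and normalized with corpus-level statistics before patch
extraction. Without that, the pretrained first-layer biases are tuned to
inputs on [0, 1] while the classifier sees centered inputs, and the
transferred features land in the wrong operating range.

## The classifier

`build_classifier()` realizes the small 3D CNN: 1–3 convolutional layers
(3x3x3, stride 1, same padding, ReLU), flatten, one fully connected ReLU
layer (16/32/64 units), and a single sigmoid output unit `p` for the
probability of "unhealthy". The two-class output described for such models
is implemented as one sigmoid unit with implicit complement `1 - p`; the
confidence score is the disparity between the two class probabilities,
`|p - (1 - p)| = |2p - 1|`. A two-unit softmax head would be equivalent and
costs more parameters. The decision threshold is 0.5, with the tie
`p = 0.5` mapped to class 1 — fixed and tested.

Training minimizes binary cross-entropy with Adam (defaults 1e-3, batch 8,
30 epochs; all configurable). A stratified `validation_fraction` (default
20%) of the training samples is held out *before* augmentation;
augmentation is applied to the inner-training portion only; the epoch with
the highest inner-validation accuracy is checkpointed (ties toward the
earliest epoch). Both the inner-validation accuracy and the held-out LOOCV
accuracy are reported, labeled separately, since they estimate different
things.

Two numerical choices deserve emphasis, both responses to optimization
failures that are easy to reproduce at this scale:

* **Flatten-feature centering.** Between flatten and the dense layer sits a
  non-trainable centering step: during training, each flatten feature is
  centered on its minibatch mean (a running mean, momentum 0.9, is applied
  at inference). ReLU activations are nonnegative, so the flattened
  features of every volume share a large common anatomical component —
  roughly ten times the norm of the between-class differences on phantom
  data. Without centering, the dense-layer optimization is dominated and
  destabilized by that component: adaptive updates either silence the ReLU
  layer within a few steps or confine learning to a knife-edge range of
  learning rates. Centering is the mean-only special case of batch
  normalization, adds no trainable parameters, and leaves every
  architectural contract (parameter counts, transfer prefixes) intact.
* **Fan-in-scaled learning rates.** Per-weight-normalized (Adam-style)
  updates move a unit's pre-activation in proportion to its fan-in. The
  flatten-to-dense matrix has fan-in of order 1e5 while the convolutions
  have fan-in 27 x channels, so a single global learning rate cannot serve
  both. Weight matrices with fan-in above a reference (2048) have their
  learning rate scaled by `ref / fan_in`, in the spirit of width-robust
  parametrizations; small tensors and biases use the nominal rate.

## Evaluation protocol

`run_loocv()` holds out one sample per fold; windows are per-image, the
normalizer is refitted on each fold's training samples, augmentation (if
any) happens after both the fold and checkpoint splits, and the held-out
sample is scored once. `run_grid_search()` repeats the complete LOOCV 15
times per grid configuration with distinct derived seeds and reports
min–max ranges and means per configuration; the default grid pairs layer
counts with filter counts (1/16, 2/32, 3/64) crossed with fully connected
widths, 9 configurations, with a `full = TRUE` escape to the 27-point
product. The best configuration is the highest mean accuracy, ties broken
toward fewer trainable parameters (small models are preferred at small n),
then grid order.

`triage_curve()` ranks predictions by confidence and reports accuracy over
the most confident `ceil(c * N)` predictions for each coverage `c`; at
`c = 1` it reproduces the overall accuracy exactly. This is the selective
prediction use case: let the model auto-classify only its most confident
cases and defer the rest.

`compare_initializations()` runs paired LOOCVs: both arms of a pair share a
derived seed, hence identical fold order, inner splits, augmentation draws
and dense-layer initialization; they differ only in the convolution
initialization (random versus transferred). Seed derivation is a
documented counter scheme (`derive_seed()`): a 31-bit linear-congruential
fold of the master seed with the (config, repeat, fold, arm) indices, so
any sub-computation is reproducible in isolation.

## The packaged benchmark

`benchmark_config()` fixes the desk-scale study conditions used by the
acceptance script and tests: 20 labeled target volumes (10/10) of
26 x 26 x 8 voxels, lesion radius 1.8–2.6, lesion contrast 0.35, Rician
sigma 0.06; a 50-volume source corpus with 50% lesion prevalence and the
wider radius range 1.4–2.6; 60 patches per corpus volume for a
single-encoder-layer (16 filters) autoencoder trained 8 epochs; a
1-conv/16-filter/16-unit classifier trained 8 epochs; 10 paired seeds.
Each paired seed draws a *fresh* target dataset (the corpus and the
pretrained autoencoder are shared): at 20 volumes, the particular
small-data draw is the dominant source of variability in any accuracy
comparison, so the replicates must marginalize over it — averaging ten
training reruns on one fixed draw would instead report that draw's
idiosyncrasy with high confidence. Sizes were chosen so the 400 classifier
fits of the paired comparison run in roughly a quarter hour on one CPU;
reduced epochs are also precisely the regime where initialization quality
matters most, which is the phenomenon under study. Augmentation is
disabled inside the benchmark for the same budget reason; its fidelity is
tested separately. The contrast and noise place the random-initialization
arm in the middle of its accuracy range — neither floor nor ceiling — so
the comparison has room to move in either direction.

## Reproducibility and configuration

Every randomized operation takes (or derives) an explicit seed, and all
seeds flow from one master seed through `derive_seed()`, so any result in
the package — a dataset, a training run, a whole grid search — is exactly
reproducible from `(inputs, configuration, seed)`. A full run
configuration (`run_config()`) bundles the stage parameters and round
trips losslessly through YAML; the command-line entry point accepts it via
`--config` and records a run log (configuration hash, seed, package and R
versions) next to its outputs. Volumes are exchanged as NIfTI with an
identity affine and float32 intensities; weights as a versioned serialized
container; normalizers as JSON; tabular results as CSV.

## Known limitations

* Phantoms have no anatomical variability between subjects; the domain gap
  between corpus and target is narrower than between large public pretraining
  data and clinic data.
* The benchmark's transfer-minus-random improvement is a noisy quantity:
  each replicate differences two 20-prediction LOOCV accuracies, so even
  the 10-replicate mean carries a standard error of a few percentage
  points, and runs at different master seeds can disagree about whether
  the benefit clears any particular threshold. At this training budget
  both arms classify on near-frozen convolution features through a learned
  dense readout, whose training noise can dominate the arm difference even
  when frozen-feature probes favor the pretrained filters.
* Volumes and weights are R doubles in memory; NIfTI output is written as
  float32.
* The checkpoint criterion (inner-validation accuracy over a handful of
  samples) is noisy at LOOCV fold sizes; this mirrors the protocol rather
  than improving on it.
* Single-threaded determinism is exact; results can differ in the last
  bits across BLAS builds.
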