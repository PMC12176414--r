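---
title: "The perturbation-robustness protocol: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The perturbation-robustness protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PerturbKit)
```

## The question the protocol answers

A binary image classifier is *robust* to an acquisition effect if its
error rate stays stable as an increasing fraction of the test images is
affected by it. PerturbKit operationalizes this with two coupled
manipulations:

* **Training variants.** From a clean training set, a variant replaces a
  random `p`% of the images by perturbed versions (`p` in 20% steps).
  Replacement rather than augmentation keeps the sample size constant, so
  differences between the baseline classifier `f` and a variant `f_p^n`
  reflect *what* the model learned, not *how much data* it saw.
* **Replicated perturbed test sets.** For each test fraction `p'` and
  perturbation kind, `R` test sets are resampled, each perturbing a fresh
  random `p'`% subset. Reporting the mean error over replicates removes
  the luck of any single draw; the replicate standard deviation indicates
  the consistency of performance.

A variant is judged more robust than the baseline when it matches the
baseline on clean data (we use a 0.03 error-rate band as "similar") and
has a significantly lower mean error on perturbed test data.

## Perturbation operators and their severities

All operators take integer images on the 0–255 scale, compute in floating
point, and quantize on output by rounding half away from zero, then
clipping. Zero-severity settings (`sigma = 0`, `EF = 1`, `angle = 0`,
`kernel = 1`) are exact identities, which the tests pin down.

* **Gaussian noise** (`sigma`, unit scale, default 0.08): the image is
  scaled to [0, 1], i.i.d. `N(0, sigma^2)` noise is added per pixel, the
  result is clipped to [0, 1] and rescaled. Clipping before rescaling is
  our choice for out-of-range handling; it keeps every output a valid
  image. The default 0.08 is the mildest noise level of the widely used
  common-corruption benchmarks: even mild noise is informative about
  whether a classifier reacts to it at all.
* **Contrast** (`EF`, default 3.3): `out = mu + EF * (x - mu)` with `mu`
  the arithmetic mean intensity of the input — extrapolation against the
  image's own mean-gray, the classic enhancement operator. Using the
  per-image arithmetic mean as the pivot is a deliberate choice; a
  constant image is a fixed point for every factor.
* **Rotation** (integer degrees, default range [−90, 90], drawn fresh per
  image): rotation about the image center, positive = counterclockwise
  with row 0 at the top, bilinear interpolation, same output shape,
  out-of-frame filled with 0. Black fill matches the dark background of
  radiographs and ultrasound.
* **Tilt** (integer degrees, default range [0, 90], per image): a
  projective warp emulating the top of the image being pushed away along
  the z-axis. The geometry is fixed by four corner correspondences: the
  top corners move inward symmetrically by `(w/2)(1 - cos theta)` (w the
  distance between corner centers) and the bottom edge stays fixed. The
  symmetric form forces the homography
  `src = a (u, v) / (q v + 1)` in centered coordinates, with
  `a = half / (half - d)` and `q = (a - 1) / (H - 1)`; at 90 degrees the
  top edge collapses to the center point and the implementation uses the
  large-`a` limit.
* **Blur** (`kernel`, `sd`; defaults 3 and 0.1): convolution with a
  normalized Gaussian kernel, edge-replicated borders. We implement the
  Gaussian form of defocus blur; a disk kernel is a near-equivalent
  description at this window size. At the default severity the kernel
  weights are numerically `(0, 1, 0)` — the operator is the identity on
  integer images. This is intentional: the protocol fixes one (mild)
  severity per kind, and the SSIM table makes the actual intensity of
  each operator measurable rather than assumed.

Severity sampling: rotation and tilt draw a fresh uniform integer angle
per image; noise, contrast and blur severities are fixed. For
simultaneous perturbations the application order is fixed to noise →
contrast → rotation → tilt → blur, because the operators do not commute;
the order is recorded with the results.

## Counting and randomness conventions

* The number of perturbed images is `k = round(p N / 100)` with
  half-up rounding; protocol percentages are rarely integral on real set
  sizes, and the convention is pinned by tests.
* The multi-perturbation training groups (default 10% per kind) are
  disjoint, which is what makes "half the training set untouched" exact
  under the defaults.
* Every randomized step draws under a child seed derived from a master
  seed and the step's coordinates (variant, replicate, image). Replicates
  are therefore reproducible independently and in any order, and one
  master seed fixes the entire experiment. Derived seeds stay below
  2^31.

## The statistical comparison

Variants are compared to the baseline with an exact Wilcoxon signed-rank
test on paired per-seed mean error rates. The exact null distribution of
the positive-rank sum is computed by dynamic programming over doubled
ranks — arithmetically identical to enumerating all `2^m` sign
assignments, and still exact under tie-averaged ranks (flagged when ties
occur). Zero differences are dropped before ranking, standard practice.
Beyond 25 nonzero pairs a normal approximation with continuity and tie
corrections takes over, flagged in the result.

The robustness comparisons are one-sided (variant better than baseline)
by default: the protocol's hypothesis is directional, and at an ensemble
size of 10 the smallest attainable one-sided exact p is
`1/1024 ≈ 0.000977`, the floor a uniform improvement reaches. A
two-sided alternative is available through the `alternative` argument.
No multiple-testing correction is applied; the report gives raw
p-values, and users comparing many variants should correct downstream.

SSIM uses the canonical parameterization — 11×11 Gaussian window with sd
1.5, stabilizers `(0.01 L)^2` and `(0.03 L)^2` at dynamic range L = 255 —
averaged over the valid (fully overlapping) window positions, i.e. the
windowed-mean variant of the index.

## The SPSA control

The adversarial control re-trains on a training set in which every image
is replaced by an SPSA-attacked version (untargeted margin loss on the
positive-class score; L∞ budget 8/255 on the unit scale). The attack
estimates the loss gradient by central finite differences along
Rademacher directions and projects onto the epsilon ball after every sign
step. The attack is run once against the clean-trained classifier before
re-training, not iteratively re-run during training. Defaults
(`nIters = 20`, `nSamples = 32`, `delta = 0.01`, `stepSize = 0.01`) are
free parameters of the implementation; the loss choice is the common one
for score-based attacks. The control's purpose is interpretive: a
classifier trained on adversarial noise should *not* become robust to
geometric perturbations, which is exactly what distinguishes
perturbation-specific learning from generic regularization.

## The synthetic generator: what it does and does not show

`generateSyntheticData()` emulates the *statistical* structure of small
grayscale diagnostic datasets: binary labels with class imbalance
(default 70% positive, typical of published chest-X-ray and ultrasound
collections), fixed disjoint train/validation/test splits, 28×28 images
by default (a 64×64 mode covers the larger-image/smaller-sample regime),
and a Gaussian background texture (mean 100, sd 20).

The class signal is a *motif* chosen to be sensitive to a specific
perturbation family:

* `corner_marker` — a bright square anchored near the top-left corner;
  its signal is positional, so rotation and tilt destroy it;
* `fine_texture` — a high-frequency centered checkerboard, erased by
  smoothing;
* `band_intensity` — a mid-intensity band, saturated by contrast
  extrapolation;
* `plain_blob` — a centered disk, invariant to rotation
  (perturbation-neutral control).

`motifSensitivityCheck()` documents the pairing. Motif amplitudes
(60–90 intensity units over background) were set once so that the
reference classifier learns each motif nearly perfectly from a few
hundred images while the sensitive perturbation demonstrably breaks it.

What passing tests on synthetic data *do* show: the protocol machinery is
correct (counts, replacement semantics, determinism), the statistics are
exact, and the robustness-recovery direction — training with a fraction
of perturbed images recovers performance on perturbed test data without
hurting clean performance — is reproduced end to end. What they do *not*
show: anything about real radiographic or ultrasound texture, realistic
class overlap, or the absolute error rates a deep network would achieve;
the synthetic motifs are far more learnable than real pathology.

## The reference classifier

The bundled learner maps unit-scale pixels through a fixed random tanh
projection (default 200 features, drawn from the training seed) and fits
a ridge-penalized linear read-out in closed form (penalty 1, intercept
unpenalized). It is deterministic given (data, seed), trains in
milliseconds, exposes real-valued scores for the SPSA attack, and clears
a <5% error floor on every synthetic motif. The protocol's "several
network architectures" averaging is realized as an ensemble of seeds:
the same architecture trained under 10 seeds, with metrics averaged and
the per-seed values feeding the paired Wilcoxon test. Any external model
can replace it by implementing `predictLabels`, `predictScores` and
`retrain`; architecture constancy across `retrain` calls is checked via
the model's hyperparameter fingerprint.

An optional validation split exists in the data model but is not used
for early stopping by default; the closed-form learner has no training
trajectory to stop.

## Problem sizes and defaults

Protocol-scale defaults copy the study design they implement: fractions
{20, 40, 60, 80, 100}, 200 replicate test sets, a 10-seed ensemble, and
analysis restricted to the 20/60/100 variants (the 40/80 variants are
enumerated and trainable but add little beyond their neighbors). The
test suite and the acceptance script run a scaled configuration — 600
training / 200 test images, 20 replicates — chosen so a full run
completes in well under a minute while every comparison retains a
comfortable signal margin; the scaling is recorded in each report's
provenance block, and `nReplicates`/`nSeeds` scale back up by config for
full-size runs.

## Known limitations

* Single-channel 2-D images only; no DICOM/NIfTI, RGB or volumetric
  support.
* One severity per perturbation per run; severity sweeps must be driven
  externally by varying the configuration.
* The SPSA control is computationally heavy at full scale (two score
  evaluations per sample per iteration per image); it is off by default
  in `runExperiment()` and intended for small control studies.
* Exact Wilcoxon inference is limited to 25 nonzero pairs before the
  flagged normal approximation takes over.
* The synthetic benchmark is a mechanism check, not a proxy for clinical
  data; conclusions about a real classifier require running the protocol
  on the real dataset.
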