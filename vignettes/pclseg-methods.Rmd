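---
title: "Detecting pancreatic cystic lesions on CT with an attention-gated U-Net"
author: "PCLseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pancreatic cystic lesions on CT with an attention-gated U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pancreatic cystic lesions (PCLs) are fluid-filled lesions that are frequent
incidental findings on abdominal CT and can be precursors of pancreatic
cancer. Detecting them automatically is hard for the usual reasons:
the pancreas has vague borders, lesions are small relative to the volume,
and a scan-level decision ("does this study contain a cyst?") must be
distilled from a voxel-level segmentation without drowning in false
positives.

PCLseg implements a complete detection pipeline for this problem:

1. **Preprocessing** — soft-tissue Hounsfield windowing (50 ± 100 HU,
   rescaled to [0, 1]) and a central in-plane crop (512 → 240 voxels at
   clinical resolution) that keeps the centre of the abdomen where the
   pancreas lies.
2. **Segmentation** — an attention-gated U-Net (background / pancreas /
   cyst) with factor-2 max-pooling, trilinear upsampling and additive
   attention gates on every skip connection.
3. **Inference** — sliding-window patch inference plus test-time
   augmentation (TTA): rotations of +7° and −11° and in-plane
   translations of +5 and +10 voxels, merged by averaging per-class
   scores before a softmax and argmax.
4. **Postprocessing** — three false-positive filters applied in order:
   an eroded abdomen mask, a pancreas-contact requirement, and a
   10-voxel minimum component size.
5. **Evaluation** — study-level sensitivity and specificity, stratified
   by cyst risk group (mucin-producing IPMN/MCN versus near-benign
   SCA/pseudocyst), plus voxel-level Dice reporting.

Everything is exercised end to end on synthetic abdominal phantoms, so
the package is fully testable without clinical data.

## The synthetic phantom

`generatePhantom()` builds a desk-scale abdomen: a superellipse
soft-tissue cross-section (30 HU) with a subcutaneous fat ring (−100 HU)
in air (−1000 HU), a vertebral bone cylinder (400 HU), an elongated
pancreas ellipsoid (55 HU), and spherical near-water cysts (5 HU) seeded
on the pancreas boundary so that every cyst touches pancreas tissue —
the geometry the contact filter expects. Per-tissue Gaussian noise
(≈10 HU) plus global additive noise (10 HU) gives a combined ≈14 HU
noise floor, in the range of clinical soft-tissue CT noise.

Two intensity choices deserve comment:

* **Tissue contrast.** The pancreas is set 25 HU above surrounding soft
  tissue and cysts 50 HU below the pancreas. Real pancreas-to-soft-tissue
  contrast can be lower; we chose a contrast of ≈1.8× the noise SD
  deliberately, because a phantom whose pancreas is statistically
  invisible at the voxel level cannot exercise any part of the pipeline.
  The intensities stay inside the plausible soft-tissue range and keep
  the ordering air < fat < cyst < soft tissue < bone.
* **What the phantom does not model.** Anatomy (organ shapes, contrast
  phases, partial-volume effects, scanner artefacts) is deliberately
  absent. Passing tests on phantoms demonstrates that the pipeline's
  machinery — windowing, cropping, patching, gating, merging, filtering,
  counting — is correct, not that the network generalises to clinical
  CT.

The default grid is 64 × 64 × 32 voxels at 1.5 × 1.5 × 5 mm — a
desk-scale stand-in for a 512 × 512 × N abdominal study. Cohort
generation stratifies the train/test split by case/control status with a
`floor(fraction × n)` rule per stratum, assigns each case a cyst risk
group, and derives every per-study seed from one master seed.

## The network

`agnetInit()` / `agnetForward()` implement a U-Net whose skip
connections pass through additive attention gates. At decoder stage
$l$, the encoder skip $x$ and a gating signal $g$ (the coarser decoder
output, trilinearly upsampled to $x$'s grid) produce attention
coefficients

$$\alpha = \sigma\!\big(\psi\,\mathrm{ReLU}(W_x x + W_g g + b)\big)
\in [0,1],$$

and the gated skip $\alpha \odot x$ is concatenated with the upsampled
decoder features. With `multidimAttention = TRUE` (default), $\psi$
emits one attention map per class; because the gate's output must have
$x$'s shape, the per-class maps are combined by averaging before the
multiplication. The per-class maps are thus primarily an
interpretability surface; the gating itself acts through their mean.

The whole network — forward pass, backward pass, Kaiming initialisation,
Adam, the learning-rate plateau schedule — is implemented in this
package on top of small C++ kernels (im2col + GEMM convolution,
max-pooling, trilinear upsampling, each with its adjoint). The backward
pass is verified against central finite differences in the test suite.
2D mode reuses the 3D kernels with a singleton z axis, 3 × 3 × 1 kernels
and in-plane-only pooling.

Patch shapes must be divisible by $2^{\text{nScales}-1}$ along the
pooled axes; indivisible shapes raise an error rather than being
silently padded.

## Training

Clinical-scale defaults: 700 epochs, batch size 4, Adam from $10^{-4}$,
learning-rate reduction after a 30-epoch validation plateau, random
160 × 160 in-plane patches. How far the rate should fall on a plateau
is a free choice; we multiply by 0.1 per plateau event with $10^{-6}$
as the terminal rate, all configurable.

The loss is the multiclass soft Dice complement

$$L = 1 - \frac{1}{|C|}\sum_{c \in C}
\frac{2\sum_v p_{cv} y_{cv} + \varepsilon}
     {\sum_v p_{cv} + \sum_v y_{cv} + \varepsilon},
\qquad \varepsilon = 10^{-5}.$$

Four training-side choices matter and are worth stating plainly,
because each was forced by an observed failure mode at desk scale:

* **Instance normalization** (`agnetConfig(instanceNorm = TRUE)`,
  default). Soft Dice is scale-free in the logits: without
  normalization the optimizer keeps inflating logit magnitudes until
  the softmax saturates, after which any class that is temporarily
  mispredicted is frozen near probability zero with a vanished
  gradient — in development this reliably killed the smallest class
  (the cyst) under every loss variant tried. Normalization between
  convolution and ReLU bounds the activation scale and removes the
  failure mode; it is standard in this network family.
* **Background stays in the Dice mean** (`diceBackground = TRUE`).
  Background supervision is what teaches the network that air, fat and
  plain soft tissue are background; trained without it, the cyst class
  claims the other dark regions of the volume wholesale (near-perfect
  voxel recall with Dice collapsing toward zero from false positives).
* **Only classes present in a patch enter the mean.** An absent
  foreground class has Dice ≈ 0 no matter what the network does; its
  term merely injects saturation pressure on that patch.
* **Class-balanced patch anchoring** (`fgBias`): with probability 0.5 a
  patch is anchored on a uniformly chosen *present class* (pancreas or
  cyst), then a uniformly chosen voxel of it, so centimetre-scale
  lesions are seen as often as the much larger pancreas. Global-norm
  gradient clipping (`gradClip = 3`) guards against the occasional
  spiked Dice gradient on nearly-empty classes.

Desk-scale test configurations use a 2-scale, 8-channel network on
32³ patches with a learning rate of $10^{-3}$; the clinical-scale defaults
remain $10^{-4}$ with the full-size network.

## Inference and TTA

Sliding-window inference tiles the cropped volume (default stride =
half the patch), averaging logits over overlapping tiles. For TTA, each
transformed copy is segmented, the per-class scores are mapped back
through the exact inverse transform (linear interpolation on score
channels, never nearest-neighbour on labels), and the passes are
averaged per voxel with the softmax applied to the *merged* scores —
averaging pre-softmax quantities is the only order for which a
post-merge softmax is coherent, and it keeps the final probabilities a
proper partition of unity. Voxels that re-enter the field of view from padding
under a transform carry a validity mask and are excluded from that
pass's average; the untransformed pass guarantees every voxel at least
one vote. Averaging makes the merge invariant to the order of the
transform list.

## Postprocessing

The three filters run in their clinical order. The abdomen mask
thresholds the raw HU volume at −500 HU, keeps the largest 26-connected
component, fills internal cavities and erodes with a voxel ball of
radius 3 (there is no canonical value for either; both are exposed in
`postprocessConfig()`). The contact filter removes
cyst components with no voxel 26-adjacent to *predicted* pancreas — the
pipeline must run on unlabeled studies, so ground truth is never
consulted. The 10-voxel size minimum is inclusive:
a 10-voxel component survives, a 9-voxel component does not. Components
are accounted for exactly once in the report, tagged with the first
stage that eliminated them.

## Evaluation

A case counts as detected if at least one surviving predicted cyst
component shares at least one voxel with the true cyst mask — the
weakest defensible overlap rule; stricter variants (minimum overlap
fraction) are configurable. Specificity is computed over
control studies only and shared across risk groups. Study-level
sensitivity/specificity are the primary metrics; voxel Dice per class is
reported alongside as segmentation-quality context.

## Problem sizes used by the test suite

The test suite and the acceptance script run entirely on phantoms:
48³ × 32 or 64² × 32 grids, 2-scale 8-channel networks, 32³ patches,
a 200-step single-phantom overfit check, and an end-to-end cohort of
30 cases + 12 controls split 2:1 into training and held-out studies.
These sizes were chosen so a complete run stays comfortable on a
single desktop CPU core; every dimension scales up by configuration
only.

## Known limitations

* The phantom's geometric simplicity means texture-, phase- or
  artefact-driven failure modes of the network are untested.
* Instance normalization makes the network's output depend on the
  statistics of the inference window; predictions from small tiles can
  differ from whole-volume passes. Desk-scale configurations therefore
  infer with generous patch sizes relative to the volume.
* The +5 / +10 voxel TTA shifts are applied along the first in-plane
  axis; the direction is a convention, configurable per transform.
* Per-patient aggregation of multiple studies is not implemented;
  metrics count studies independently.
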