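---
title: "Two-step segmentation of thoracic organs at risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step segmentation of thoracic organs at risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the two-step design

Radiotherapy planning for lung cancer requires contouring the organs at risk
(OARs) on axial CT: both lungs, the heart, the spinal cord, the trachea and
the esophagus. Five of these are comparatively easy targets for a
convolutional network — they are large, high-contrast, or anatomically fixed.
The esophagus is not: it is small (a few hundred mm² per slice), its wall is
nearly isointense with the surrounding mediastinum, its lumen is variably
air-filled, and it drifts toward the patient's left between the carina and
the cardia.

`thoraxseg` implements a coarse-to-fine division of labor:

1. **Stage 1** — a dense-block U-shaped network reads the full windowed
   slice and segments the five "easy" OARs (6 output classes with
   background).
2. **Localization** — the esophagus is reliably adjacent to the trachea, and
   the trachea is an almost unmissable air column. The per-slice centroid
   ("center of gravity") of the predicted trachea, shifted 5 mm left and
   5 mm up (image convention: left = decreasing column, up = decreasing
   row), centers a 64×64 crop that leaves room for the esophagus.
3. **Stage 2** — a residual attention network segments esophagus vs
   background inside the crop, where the class imbalance is milder and the
   network capacity is spent on the one hard boundary.
4. **Paste-back** — the stage-2 mask is written into the stage-1 labeling.
   The esophagus is *exclusively* stage 2's: stage-1 esophagus voxels are
   discarded everywhere, and stage-2 foreground never overwrites another
   organ's label (precedence protects the air columns from each other).

A 7-class variant of stage 1 (esophagus as an extra class) exists solely as
the one-step ablation, and a plain U-Net with the same I/O contract is the
baseline comparator.

## Preprocessing

CT volumes in Hounsfield units pass through a mediastinal display window:
width 400 HU, level 40 HU, mapped linearly onto [0, 255] with clipping
(`apply_window()`), then onto [0, 1] for network input. Windowed values stay
real-valued; quantization to 8 bits happens only if slices are exported as
PNG. Expert per-organ masks are merged into one exclusive integer labelmap
with the fixed precedence trachea > cord > esophagus > heart > lungs —
networks are prone to confusing the esophagus with the adjacent trachea, so
the air-column labels must never be silently overwritten by a large
soft-tissue mask.

## The residual attention block

Feature maps are `(H, W, C)` (plus a batch axis). Each block's main path is
3×3 conv → ReLU → 3×3 conv, followed by a cascade of two gates, **spatial
first, channel second** (the channel gate pools the spatially gated map, not
the raw one):

* **Spatial attention**: per-position max- and mean-pooling across channels
  gives a 2×W×H stack, convolved (7×7 by default, configurable) and squashed
  by a sigmoid into a per-position gate in (0, 1) that multiplies every
  channel.
* **Channel attention**: global max- and mean-pooling over positions give two
  C-columns; a *shared* 1-D convolution of kernel length
  `K = max(1, round(log2 C))` (round half-up; same-length zero padding,
  asymmetric when K is even) is applied to each, the results summed and
  squashed into a per-channel gate that multiplies every position. The
  kernel grows logarithmically with the channel count so deeper layers fuse
  information across more channels.

The block output is main path + shortcut: the raw input in *identity* mode
(requiring equal widths — with a zero main path the block is exactly the
identity), or a 1×1 convolution in *convolution* mode. The encoder
alternates convolution and identity blocks with stride-2 convolution
downsampling; the decoder alternates nearest-neighbor upsampling (with a 3×3
merge convolution absorbing the skip concatenation) and identity blocks.
Long skip connections concatenate each encoder level onto the matching
decoder level. Because both gates are sigmoids, every main-path activation
is bounded elementwise by its pre-gate magnitude — a property the test suite
asserts.

## Stage-1 dense U-net

Encoder stages are dense blocks: every layer's 3×3 convolution output
(growth-rate channels) is concatenated onto the running stack, so a block of
`L` layers widens `w` input channels to `w + L·g`. Transition layers (1×1
compression convolution at factor 0.5, then a stride-2 convolution) link the
stages; the decoder mirrors with upsampling, skip concatenation, and merge
convolutions. Defaults are 4 stages, 4 layers per block, growth 12 — a
deliberately parameterized stand-in for the heavier published dense
architectures; every structural number is config, and the scaled-down runs
in this package use smaller settings (3 stages, 2 layers, growth 6).

## The crop localizer

All offsets are specified in millimetres and converted by the in-plane
spacing, so behavior is resolution-independent:

| parameter | default | meaning |
|---|---|---|
| `crop_size` | 64 px | side of the stage-2 window |
| `shift_left_mm`, `shift_up_mm` | 5, 5 | systematic centroid offset leaving room for the esophagus |
| `jitter_range_mm` | [0, 4] | training-time displacement magnitude |
| `fallback_step_mm` | 1 | per-slice step when chaining from the previous center |

Training crops are centered on the **label** trachea centroid plus a random
displacement with uniform magnitude on [0, 4] mm and uniform direction —
emulating the stage-1 localization error the crop network must tolerate
(the magnitude range matches the typical stage-1 surface distance).
Inference crops use the **predicted** trachea centroid with no jitter.
Slices with an empty trachea mask chain from the previous slice's center,
stepping 1 mm per slice; the step direction defaults to image-left,
following the esophagus drift below the carina, and is config
(`fallback_direction`). The crop window is half-open and anchored at
`round(center) − size/2`; out-of-image area is zero-padded and recorded so
paste-back is exact.

## Losses and optimization

The loss is the mean of a soft-Dice term and a cross-entropy term
(`dice_weight = 0.5`). The cross-entropy is **class-balanced**: every class
present in the target contributes equally, whatever its voxel count (in the
binary stage-2 case, foreground and background each contribute half). The
thin organs occupy well under 1% of a slice; with plain frequency-weighted
cross-entropy their gradient signal is negligible at small step counts and
the trachea — the anchor of the whole second stage — is learned far too
slowly. Class balancing is the standard remedy for this imbalance and is
part of the package's loss definition, not a tuning knob. Optimization is
Adam (lr 1e-3 to 3e-3 in the shipped configurations), batch size 1,
slice-wise 2-D training, fully seeded: weight initialization, shuffling and
crop jitter all derive from explicit seeds, and repeated runs are
bit-identical on one CPU thread.

The engine itself is a compact reverse-mode autodiff over `(H, W, C, N)`
arrays written for this package, with im2col + GEMM convolution kernels in
C++ (RcppArmadillo). Gradients of every primitive are verified against
central finite differences in the test suite.

## Geometric metrics

`dsc`, `hd95` and `asd` are computed in 3-D per patient volume with
anisotropic spacing — the 5 mm slice thickness makes the 2-D/3-D choice
material, and 3-D is the benchmark convention. Choices that a metric value
depends on, stated explicitly:

* **Surface** = mask voxels with a 6-connected background or out-of-volume
  neighbor; distances are voxel-center to voxel-center.
* **HD95** = max over the two directions of the 95th percentile (linear
  interpolation, so a singleton surface reproduces its exact distance) of
  directed surface distances. A pooled-distances variant and a slice-wise
  2-D variant are exposed as arguments for sensitivity checks.
* **ASD** = symmetric average: all directed distances from both surfaces,
  summed, divided by the total surface count.
* Organs empty in both volumes score DSC 1 with *missing* distances; empty
  in exactly one, DSC 0 with missing distances. Distances are never
  silently reported as 0.
* The fast path reads an anisotropic separable Euclidean distance transform
  (Felzenszwalb's lower-envelope algorithm, C++); the suite holds it to
  within 1e−9 mm of an O(n²) all-pairs oracle.

Cohort comparisons use the paired Wilcoxon signed-rank test per organ and
metric (exact distribution when ≤ 25 non-zero differences without ties;
all-zero differences give p = 1 by convention).

## The synthetic phantom

Clinical CT with expert contours cannot ship with a package, so every stage
is exercised on a seeded parametric thoracic phantom. Each axial slice
contains: a soft-tissue body ellipse (40 HU) on air (−1000 HU); two lateral
lung ellipses (−750 HU) tapering toward apex and base; a contrast-enhanced
heart ellipse (90 HU, central-anterior); a posterior spinal cord disk
(45 HU) inside a bony ring (700 HU); a central air-filled trachea
(−950 HU); and an esophagus disk whose wall is soft tissue (40 HU) and whose
lumen is air over a per-patient sampled fraction of its area (the label
always covers the full disk — air filling changes intensity, never
anatomy). Below a configurable carina slice the esophagus drifts image-left
at a per-patient rate of 1.6–2.6 mm per slice, and it always sits within a
sampled 1–4 mm wall-to-wall gap below the trachea. Per-slice centers jitter
by up to 1 mm; Gaussian noise (sd 20 HU) is added; all tissue intensities
are config so low-contrast regimes can be stressed.

What the phantom *does* emulate: the topology and contrast statistics the
method depends on (air columns, laterality, posterior cord in bone, small
variably-filled esophagus adjacent to and left of the trachea below the
carina, 5 mm slices). What it does *not*: texture, organ shape variability
beyond ellipses, breathing or cardiac motion, metal or beam-hardening
artifacts, tumors. Passing phantom tests therefore demonstrates that the
pipeline's machinery is correct and that the two-step design direction holds
under controlled conditions — not clinical-grade accuracy.

An anatomical contract checker validates every generated sample from its
own labels (lung laterality, cord posterior of heart and trachea inside a
bright ring, trachea/esophagus disjointness and adjacency, left drift below
the carina, single connected component per organ per slice). Lung naming
follows the image convention (left lung = smaller columns); flip the
interpretation if treating the volume as radiologically displayed.

## Scaled-down study conditions

The end-to-end benchmark (`phantom_benchmark()`) keeps the cohort structure
of the target study — 39 training, 8 validation, 12 test patients, split by
patient — at sizes a single CPU handles in minutes: 128×128 slices at a
preserved 384 mm field of view (3 mm pixels, 5 mm slices), 12 slices per
patient, stage-1 nets of ~20k weights trained one epoch over 3 slices per
patient, and the stage-2 attention net (~17k weights) trained 3 epochs over
6 crops per patient. These sizes are the package's chosen phantom-scale study
conditions; the directional claim (two-step esophagus DSC above the
one-step 7-class variant and at or above the baseline U-Net) is asserted by
majority over three master seeds, since individual scaled-down runs are
stochastic.

## Numerical and degenerate-input conventions

* Stage-1 argmax ties break to the lowest class index; the stage-2 decision
  threshold is 0.5 on the sigmoid (config).
* An empty trachea prediction on every slice yields an empty esophagus and
  a warning rather than an error.
* Crops whose window leaves the image are zero-padded, never shrunk.
* `K = log2(C)` rounds half-up with a floor of 1, so K is exact at powers
  of two; even K uses asymmetric zero padding.
* Both-empty masks define DSC = 1; surface metrics on empty masks raise a
  typed error (`ts_empty_mask_error`) and surface as missing values in
  reports.
* NIfTI is the canonical on-disk format ((z, y, x) internal order, spacing
  from the header); PNG stacks with a JSON sidecar are read-only fixtures.
  R-style 1-based indexing is used throughout the API.

## Known limitations

* 2-D slice-wise networks: no through-plane context beyond the localizer's
  slice chaining.
* The engine is CPU-oriented R + BLAS; it is sized for the phantom study,
  not for 512² clinical volumes at full capacity.
* The phantom's analytic geometry cannot surface failure modes driven by
  real-tissue texture or pathology.
* DICOM / DICOM-RT are out of scope; convert to NIfTI upstream.
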