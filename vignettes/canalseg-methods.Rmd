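---
title: "Micro-CT-guided root canal segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-CT-guided root canal segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Root canal treatment planning needs an accurate 3D model of the canal
system, but the clinical imaging modality — cone-beam CT (CBCT) at 80-200
µm voxels — blurs exactly the structures that matter: apical canal
segments, accessory canals, isthmuses. Micro-CT at ~30 µm resolves them
easily, but only ex vivo. `canalseg` implements the resulting training
strategy for extracted-tooth data: segment the tooth and its canal system
on micro-CT by simple thresholding (where it works), carry those
high-quality masks onto the paired CBCT grid by rigid registration, and use
them as ground truth to train a CBCT segmentation network. The package
covers the full chain — synthetic paired data, label transfer, a two-stage
nested-U segmentation cascade, overlap and surface metrics, voxel-size
resampling studies, and connected-component post-processing — so every
claim about the method can be exercised end to end on seeded phantoms.

## Volumes and geometry

All images are `volume3d` objects: a numeric array in column-major
`(x, y, z)` order (axial planes at fixed `z`), an isotropic voxel size in
mm, and a world origin, under the voxel-center convention — index
`(i, j, k)` (1-based) sits at `origin + (c(i, j, k) - 1) * voxel_size`.
NIfTI files are written RAS+ with a diagonal sform and reoriented to that
canonical frame on read. Crop boxes are half-open index intervals.
Resampling covers the same world extent (`ceiling(n * s_in / s_out)`
voxels per axis), interpolates at output voxel centers (trilinear or
nearest), and fills out-of-support sites with the image minimum, which is
the air background around an isolated tooth. Binarization sends threshold
ties to foreground.

## The synthetic phantom

No public paired micro-CT/CBCT tooth dataset exists, so the package
generates its own study conditions. A `phantom_spec` describes a tooth as
an elliptical crown (enamel shell over a dentin core) on 1-3 tapered root
trunks, each with a tapering canal lumen that opens into a pulp chamber;
options add a quadratic apical bend, an accessory canal, an isthmus sheet
between two canals, and a C-shaped arc sweep (with a fused root trunk, as
in C-shaped molars). Three geometric choices are deliberate:

* the canal stops 0.3 mm short of the anatomical apex (the apical
  constriction) and accessory canals stop 0.15 mm short of the root
  surface, so the whole canal system is a closed interior cavity — exactly
  the condition under which single-threshold micro-CT segmentation plus
  cavity classification recovers it;
* root trunks extend into a cervical merge zone and lumens converge into
  the chamber, so no lumen is ever exposed at the root-crown junction;
* the crown cross-section is elliptical (y/x = 0.85). A perfectly round
  tooth makes the rigid registration problem degenerate in the axial
  rotation; real teeth are not round, and neither are these.

Phantoms are desk-scale: root lengths 3.5-5.5 mm and crown radii
1.3-1.8 mm rather than the ~12 mm roots of natural teeth. At the 30 µm
micro-CT voxel this keeps a tooth near 3M voxels instead of ~50M, which is
what makes the full pipeline (including network training) runnable in
minutes on one CPU. Tissue proportions, intensity ordering
(enamel 2000 > dentin 1000 > canal/background 100, micro-CT noise sd = 2%
of the dentin mean) and the anatomy classes are preserved; absolute
metric values on these phantoms are not comparable to values measured on
natural teeth.

The CBCT simulator degrades the micro-CT rendering by a rigid pose offset,
an isotropic Gaussian PSF (default sigma = one target voxel), linear
downsampling to 200 or 80 µm, and additive Gaussian noise (default 5% of
the dentin mean). It deliberately omits beam hardening, scatter, cupping
and metal artifacts; what it does reproduce is the mechanism that drives
the resolution findings — canal-dentin contrast separation shrinks as the
voxel grows, which the test suite asserts directly. Cohorts draw specs
from seeded ranges with random poses (rotations up to 10 degrees,
translations up to 1 mm) and are bit-reproducible per seed.

The manual-annotation surrogate `degrade_labels` encodes the documented
behaviour of contrast-limited human contouring — systematic
over-estimation of boundaries — as morphological dilation plus optional
seeded boundary jitter. With zero jitter the degraded mask contains the
original, so its recall is 1 while precision falls. No quantitative model
of human annotation error is claimed; comparisons against this arm are
directional only.

## Micro-CT-guided label generation

`threshold_uct` thresholds the micro-CT (global value or a global Otsu cut
over the full 3D histogram), keeps the largest 26-connected component, and
classifies background components that do not reach the volume border as
the canal system. `extract_surface_points` takes voxel centers with a
face-adjacent background neighbour. `icp_register` is trimmed point-to-point
ICP: nearest-neighbour correspondences, the worst 10% of matches dropped,
closed-form rigid alignment by SVD of the cross-covariance
(determinant-corrected), stopping when the trimmed RMS improves by less
than 1e-4 mm or would increase (the previous transform is kept, so the
residual log is non-increasing by construction). Because a tooth is close
to axially symmetric, a single centroid initialization can settle in the
wrong axial-rotation basin; registration therefore starts from four coarse
z-rotations (0/90/180/270 degrees) and keeps the start with the lowest
final residual. `transfer_labels` pulls each target voxel center back
through the inverse transform, interpolates the mask linearly as a 0/1
field and binarizes at 0.5 — the smoothing behaviour of resolution
normalization; nearest-neighbour transfer is available by flag.

`groundtruth_fidelity` quantifies what registration-to-a-coarser-grid does
to the ground truth itself: transfer at identity pose to a target voxel
size, transfer back, Dice against the original. For tube-like canal masks
this is 1 at the native size and non-increasing in voxel size — fine
detail lost at 200 µm simply no longer exists in the labels, which is why
quantitative metrics and visual quality can disagree across voxel-size
groups.

## The segmentation cascade

The network is a nested-U: an outer encoder-decoder whose stages are
themselves small residual U-blocks (RSU), with deep supervision — a 1x1
side output from every decoder stage and the bottom, upsampled to full
resolution and fused by a 1x1 convolution into the final map. All
activations are ReLU, outputs are sigmoids. Processing is 2D on axial
slices (the nested-U design is natively 2D and axial crops are the natural
unit here); 3D convolution is an extension point, not implemented. Because
this R stack has no deep-learning framework, the forward and backward
passes are implemented in the package itself over im2col + GEMM
RcppArmadillo kernels; every backward pass is verified against central
finite differences in the development history, and determinism is exact on
one device.

Two configurations share one interface: `tiny` (2 encoder stages + bottom,
~28k parameters) used for every desk-scale experiment and test, and
`full`, a full-size nested-U configuration
(6-level outer U, RSU depths 7 to 4, up to 512 channels). Training uses
Adam at learning rate 1e-3, mini-batches of 8
slices, per-volume min-max intensity normalization, and joint image/label
augmentation by seeded in-plane rotation (±15 degrees) and centred random
crop-resize (fraction 0.9-1.0). The loss is deep-supervised binary
cross-entropy averaged over all outputs plus a soft-Dice addend with
default weight 0.5: canal foreground occupies around 1% of a masked crop,
and plain BCE is poorly conditioned for such thin tubular structures. The
addend weight is configuration-exposed; setting it to 0 recovers pure BCE.
The best-validation-epoch (or best-training-epoch) checkpoint is returned.
A `slice_stride` option trains on every k-th axial slice; the desk-scale
profile uses stride 2, inference always uses every slice.

The cascade runs tooth-first: stage TS segments the tooth from the CBCT
crop (binarize at 0.5, keep the largest component); the crop is then
masked to the predicted tooth — outside voxels set to the per-volume
minimum rather than cropped, which preserves grid alignment with the
labels — and stage RCS segments the canal inside it. Canal output is
restricted to the predicted tooth mask, so containment holds on every
input, including empty predictions (returned with a warning flag, never an
error). The two stages are trained independently.

## Evaluation

`overlap_metrics` computes, from exact voxel counts,

$$DSC = \frac{2\,|V_{gt} \cap V_{seg}|}{|V_{gt}| + |V_{seg}|},\qquad
SEN = \frac{|V_{gt} \cap V_{seg}|}{|V_{gt}|},\qquad
IOU = \frac{|V_{gt} \cap V_{seg}|}{|V_{gt} \cup V_{seg}|}.$$

Degenerate inputs are conventions, stated rather than hidden: two empty
masks score 1 on all metrics; an empty ground truth with a non-empty
prediction reports SEN as 0 with a flag. `surface_deviation` measures
point-cloud-to-point-cloud signed distances between boundary voxel
centers (positive outside the ground-truth solid), an approximation to
mesh-based surface inspection that is adequate at or below voxel-size
resolution; the ±0.5 mm (tooth) and ±0.2 mm (canal) bands are reporting
ranges only — no data are discarded. `compare_arms` tabulates paired
means, sds and differences without hypothesis tests.

## Post-processing

Canal predictions in molars occasionally contain false-positive objects in
the coronal dentin. `connected_components` labels objects under 6- or
26-connectivity (default 26); `remove_false_positives` offers three
automatic policies — keep the k largest, drop small components, or keep
components whose centroid lies in a region mask, with
`radicular_region` (the tooth below its widest axial cross-section, a
cervical-plane surrogate) as the intended default region. All policies are
subsets of their input and idempotent. The original workflow removed such
objects semi-manually; the policies make that step reproducible.

## Numerical and design notes

* Interpolation outside the source support uses the image minimum;
  mask transfer fills with 0.
* Binarization ties go to foreground; mask transfer binarizes at 0.5.
* ICP defaults: 100 iterations, tolerance 1e-4 mm, trim fraction 0.1.
  These are conventional trimmed-ICP settings and are all overridable. Scale estimation is not
  implemented (rigid only).
* Max pooling handles odd extents with clamped windows; inference pads
  slices to the network's downsampling multiple (16 for `tiny`) with
  background and crops back. Training crops must already be multiples of
  that factor — `make_pairs(axial_size = 48)` is the desk-scale default.
* Seeds flow top-down: a cohort seed derives per-tooth spec, noise and
  pose seeds below 2^31; training seeds initialization, shuffling and
  augmentation. Identical seeds give byte-identical outputs on one device.

## Desk-scale experiment sizes

The bundled experiments are sized for a single CPU: overfit sanity uses
one phantom at 80 µm with 48x48 crops; the two-arm comparison uses
cohorts of 8 single-rooted phantoms (6 train / 2 test) at 80 µm, the tiny
network, 10 epochs at slice stride 2; the reproduction driver
(`repro_run`) defaults to 3 + 1 phantoms and 12 epochs. These sizes are
the package's declared study conditions for synthetic data; the
`full_scale` profile (full network, 400 epochs, 160x160 crops, 28 teeth)
exists for users with the time to run it.

## What passing tests do and do not show

The phantom generator emulates geometry, tissue contrast, resolution loss
and annotation inflation — not scanner physics, surrounding bone,
neighbouring teeth, or natural anatomical variability. Tests passing on
phantoms therefore validate the machinery (label transfer fidelity, metric
arithmetic, cascade containment, the direction of the label-quality
effect, the monotone resolution effect), not clinical performance, and the
accuracy levels attainable on real extracted-tooth datasets cannot be
inferred from them. Directional findings — micro-CT-guided
labels beating dilated labels on Dice/IoU while losing on sensitivity, and
ground-truth fidelity falling with voxel size — are the quantities this
package is designed to reproduce.
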