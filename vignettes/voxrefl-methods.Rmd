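---
title: "Voxel-wise reflectivity analysis of T1-weighted tube phantoms: models and methods"
author: "voxrefl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise reflectivity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxrefl)
```

## The measurement problem

Gadolinium-based contrast agents shorten the longitudinal relaxation time
T1 of water protons and therefore brighten T1-weighted spin-echo images.
When the uptake of a targeted agent is compared between two cell samples —
a *test* sample (e.g. cancer cells incubated with a tumor-targeted
conjugate) and a *control* sample — each sample is embedded in agarose
inside a 0.5 mL tube and both tubes are scanned. The quantity of interest
is the percent signal difference, called the **reflectivity** R.

The traditional readout draws a region of interest in each tube and
compares the two ROI means:

$$ R \;=\; \frac{\overline{\mathrm{Test}} - \overline{\mathrm{Control}}}
               {\overline{\mathrm{Control}}} \times 100 . $$

Manual ROI placement is irreproducible and wastes most of the voxels.
voxrefl instead establishes a dense voxel-on-voxel correspondence between
the two tubes and computes the reflectivity as a ratio of sums over all N
matched voxels, together with a per-voxel map:

$$ R \;=\; \frac{\sum_{i=1}^{N} (I_i - g_i)}{\sum_{i=1}^{N} g_i}
   \times 100 , \qquad
   r_i \;=\; \frac{I_i - g_i}{g_i} \times 100 , $$

where $I_i$ is the test-tube signal and $g_i$ the control-tube signal at
matched voxel $i$. On any fixed common mask the global form is
algebraically identical to the ROI form applied to the two mask means —
the gain of the automated method lies in the VOI extraction, the
registration that justifies pairing $I_i$ with $g_i$, and the voxel-wise
map, not in the formula itself. The test suite asserts this identity to
1e-9 relative.

Because the absolute signal scale of a scan depends on coil loading and
scanner gain, every scan carries one tube of plain water and all voxel
values are divided by the mean water signal of that scan before any
comparison (`normalizeByWater()`); reflectivity is invariant under this
normalization when both scans share a common scale, and the water means
are recorded in the result's provenance.

## Pipeline stages

`runPipeline(testScan, controlScan, config)` executes, in order:

1. **Background removal** — a global threshold maximizing the
   between-class variance of a 256-bin histogram (Otsu's criterion).
   Deterministic, parameter-free, and checkable against exhaustive search
   over all cuts, which the test suite does.
2. **Tube detection / 3D region growing** — 26-connected components of
   the foreground (equivalently, region growing from any in-tube seed with
   the inclusion band `[threshold, Inf)`); components within a voxel-count
   band become `TubeVOI` objects. Roles (analysis tube vs water tube) come
   from configuration: explicit seed points or a left-to-right centroid
   ordering, because the tube arrangement is an experimental convention,
   not something the image can reveal.
3. **VOI extraction** — each tube's bounding box padded by 4 voxels,
   cropped with the origin updated so physical coordinates are unchanged.
4. **Interior distance maps** — for every voxel inside a tube, the
   minimum Euclidean distance to the tube boundary (next section). These
   are the registration feature images: they depend only on tube *shape*,
   not on the signal level being measured.
5. **Affine registration** — a 12-degree-of-freedom transform (3x3
   matrix + translation about the reference-tube centroid) maximizing the
   mutual information of the two distance maps, optimized by L-BFGS-B.
6. **Elastic refinement** — a cubic B-spline free-form deformation with
   four-stage multiresolution, also under L-BFGS-B (details below).
7. **Resampling** — the test VOI is interpolated onto the control grid
   through the composite transform; voxels mapping outside the test domain
   are flagged invalid, never zero-filled.
8. **Reflectivity and color map** — the sums above over the analysis
   mask, then a symmetric diverging color rendering of the voxel map.

## Interior distance maps

The boundary set is defined on the voxel grid: a mask voxel is boundary if
any of its 6 face neighbours is background (the grid border counts as
background), and boundary voxels carry exactly 0. Interior values are the
Euclidean distances to that boundary set, computed by a fast-marching
front: a min-heap sweeps outward from the boundary and each voxel carries
the coordinates of its provisional nearest boundary voxel, so a
neighbour's tentative value is measured straight back to that anchor
(vector/anchor propagation in the style of Danielsson's distance
transform, with 26-connected propagation, anisotropic spacing in mm, and
heap ties broken by voxel index for cross-platform determinism). Unlike a
first-order upwind Eikonal stencil, anchor propagation does not accumulate
O(h) error at medial ridges: on the fixture set (random spherical blobs up
to 20^3) the worst deviation from an all-pairs brute-force oracle is below
0.05 mm, and a 3x3x3 cube evaluates exactly (26 boundary voxels at 0,
center at 1.0). Distances double exactly when the spacing doubles and
translate exactly with the mask, which the property tests exercise.

## Similarity metrics

`mutualInformation()` is defined on a bins x bins joint histogram of the
masked values, $\mathrm{MI} = \sum p(a,b) \ln\!\big[p(a,b) / (p(a)p(b))\big]$
with $0 \ln 0 \equiv 0$, in nats. Two binning modes are exposed:

* **hard** (default): each sample falls in one bin. This is the textbook
  definition the oracles check — MI(X, X) equals the histogram entropy,
  the perfectly dependent two-bin case gives $\ln 2$, and exactly
  factorizing joints give 0.
* **soft**: each sample splits linearly between the two adjacent bins in
  each image (partial-volume weighting). The hard-binned metric is
  piecewise constant in the transform parameters, so the affine optimizer
  uses the soft variant internally, with binning ranges frozen at the 1st
  and 99th percentiles of each input before optimization so the metric
  surface does not shift between evaluations. 32 bins by default.

## Affine stage

The transform is parameterized as the 9 matrix entries (offsets from the
identity) plus 3 translations about the reference-tube centroid, with the
translation initialized at the centroid difference so the optimizer starts
from coarse alignment. L-BFGS-B runs with finite-difference gradients on
the soft MI (dense sampling of every voxel in the cropped feature images;
no stochastic sampling, so runs are deterministic), box constraints
(matrix offsets within +/-0.35, translation within +/-20 mm), and an
improving-value trace. If the optimum does not improve on the
initialization the initialization is returned, flagged. Distance maps are
cropped to the mask bounding box plus a 4-voxel margin first, so the cost
scales with the tube rather than the scan.

On the default phantom conditions (64^3 grid, 1 mm voxels, Rician noise
sigma 2 on a 100 a.u. tube), 20 seeded draws of translation up to ~5
voxels, rotation up to 10 degrees and per-axis scale 0.9-1.1 are recovered
with median target-registration error below half a voxel (asserted in the
acceptance-style tests; the misregistration is evaluated by composing the
recovered transform with the known applied one).

## Elastic stage and its identifiability limit

The free-form deformation is a uniform cubic B-spline displacement field:
zero coefficients give the identity, and the displacement at a point is
the tensor-product sum of its 4x4x4 surrounding control coefficients. The
composite transform is `affine(x + warp(x))`. Four multiresolution stages
shrink the images by factors 8/4/2/1 with Gaussian smoothing sigmas
4/2/1/0 voxels; shrink factors are clamped so every stage keeps at least
~8 voxels per axis (tube VOIs are small), and the control spacing starts
at a quarter of the VOI extent, halves per stage, and is floored at four
voxel spacings. Coefficients are carried between stages by evaluating the
coarse field at the finer control points.

Two design choices here deserve their rationale:

* **Metric.** The elastic default is *mean-squares on the distance maps*
  (with the exact analytic gradient with respect to the control
  coefficients, computed in compiled code), not an intensity metric on
  the T1-weighted volumes. The intensity difference between the test and
  control tubes is precisely the quantity being measured; an elastic
  optimizer matching intensities has both the freedom and the incentive
  to shrink that difference, biasing R toward zero. Distance maps carry
  the same geometry with no memory of the signal level, and they give a
  usable gradient everywhere inside the tube (the field of a distance
  cone), not just at the wall. An MI mode (`metric = "mi"`, with
  finite-difference gradients) remains available for feature images on
  different value scales.
* **Regularization.** A homogeneous cylinder determines a deformation
  only up to its symmetry group: azimuthal rotations and mid-tube axial
  slides change neither the shape nor any homogeneous-intensity image, so
  no metric of this family can recover those components. A ridge penalty
  `lambda * mean(coef^2)` (default `lambda = 0.05`) anchors the
  undetermined components at the minimal-deformation solution and stops
  the optimizer from chasing sub-voxel boundary voxelization jitter; the
  control-spacing floor serves the same purpose. The defaults were fixed
  by a small synthetic validation study (bending warps of known
  ground truth at the default phantom conditions) trading flexibility
  against that identifiability limit; with them, applied warps of up to
  ~2 voxels with recoverable (cross-section shift) structure come back
  with mean residual displacement below half a voxel. Ground-truth warps
  used in the recovery tests are built from in-plane shifts varying along
  the tube axis for exactly this reason — a fully random displacement
  field contains azimuthal components that are unrecoverable *by
  construction*, for any method, on this geometry.

## Reflectivity masks and partial volume

The sums run over the control-tube mask intersected with the voxels the
resampling marked valid in both volumes; voxels with non-positive control
signal are flagged in the map and excluded. The mask is additionally
eroded by one voxel by default (`erodeVoxels` in `pipelineConfig()`):
voxels on the tube wall mix tube and background signal over the
interpolation stencil, and for a 6 mm tube at 1 mm spacing that
partial-volume shell is a large fraction of the cross-section. Erosion
trades a thin shell of voxels for unbiased sums; setting
`erodeVoxels = 0` disables it.

Under the default study conditions (test tube at 1.2x the control signal,
a 3-voxel shift + 5 degree rotation + ~1 voxel bend applied to the test
scan), the pipeline reads back R = 20 +/- 2%, and two scans of identical
samples with independent noise give |R| < 0.5%. Disabling registration on
the misaligned pair corrupts R by tens of percent, which is the point of
the registration stages.

## T1 mapping and relaxivity

An arrayed-TR spin-echo series follows the saturation-recovery model
$S(\mathrm{TR}) = s_0\,(1 - e^{-\mathrm{TR}/T_1})$; the constant
$e^{-\mathrm{TE}/T_2}$ factor of the fixed echo time is unidentifiable
from a TR array and is absorbed into $s_0$, which is harmless to $T_1$.
`fitT1Map()` fits each voxel by Levenberg-Marquardt with the analytic
Jacobian, initialized from a log-linearized estimate and bounded to
T1 in [50, 10000] ms (the physical range for agarose/cell phantoms at
high field; configurable). Voxels with no usable TR dependence (constant
signal, or signal not increasing with TR) are excluded with a reason code
rather than fitted. Noiseless nine-TR data (the 9.4 T protocol,
TR = 6000 ... 800 ms) is recovered to machine precision; at 2% Rician
noise the median relative T1 error stays under 5%, and the error falls
monotonically along an SNR ladder of 10/25/50/100. The 3 T five-TR
protocol runs through the same interface, since nothing in the fit is
field-strength specific.

Relaxivity is the slope of $R_1 = 1000/T_1(\mathrm{ms})$ (s^-1) against
agent concentration (mM), by ordinary least squares; the intercept is the
diamagnetic rate of the matrix. Exact collinear inputs return the
constructed slope with $r^2 = 1$ to 1e-10 (the suite uses a line of slope
3.75 mM^-1 s^-1, the relaxivity scale of a clinical gadobenate
dimeglumine control at high field). T1-based enhancement between two
samples defaults to the percent change of mask-mean $R_1$ (agents shorten
T1, so more uptake raises $R_1$); a signal-mode alternative applies the
ROI reflectivity formula to T1-weighted means, and the mode is recorded
on the result.

## Gadolinium quantification

The xylenol-orange assay reads free Gd(III) from the A573/A433 absorbance
ratio through a linear calibration. The published workflow quantifies
concentration as $A + B \times \mathrm{ratio}$ with $A = 3.0826$,
$B = 1.0944$, coefficients "retrieved from" the calibration line
$Y = 0.3244X - 1.0944$. Algebraically, the inverse of that line is
$(\mathrm{ratio} + 1.0944)/0.3244$, i.e. coefficients $1/0.3244 = 3.0826$
(matching the published A) and $1.0944/0.3244 = 3.3736$ (not the
published B; the printed B appears to transcribe the line's intercept
magnitude instead). Both readings are first-class: `as_printed` mode
(default) reproduces the published quantification verbatim and emits a
warning flagging the inconsistency; `inverse_consistent` mode derives the
coefficients from the line so that forward mapping and inversion compose
to the identity to 1e-10. The assay section also prints the slope once as
0.3224; both slopes are accepted via the constructor, with 0.3244 (the
one tied to A = 3.0826) as default. Concentration units follow the
calibration data and are carried as metadata.

## Synthetic phantoms: what they emulate, and what they do not

`generatePhantom()` builds the study scene directly: cylindrical tubes
with assigned signals (or T1/s0 pairs) on an axial grid, background, and
Rician noise — the magnitude of two independent Gaussian components added
to the signal, matching magnitude reconstruction of complex MR data. The
default layout is one test, one control and one water tube (radius 6 mm,
length 40 mm) on a 64 mm isotropic 1 mm grid; default signals 120/100/60
a.u. put the test tube at 1.2x the control with water dark, as on
T1-weighted images, and noise sigma 2 gives SNR 50 on the control tube.
Known misalignments are applied by evaluating the continuous cylinder
model at the deformed location `affine(x + warp(x))` — exact resampling
of the ideal scene, free of interpolation blur — and the applied
transforms are returned as ground truth. Voxel membership is by voxel
center, which makes cylinder volumes analytically checkable (the
voxelized count converges to pi r^2 L as spacing shrinks). Identical
specs, including the seed, are bit-identical, and generation restores the
caller's RNG state.

The simulator does *not* model B0/B1 inhomogeneity, gradient
nonlinearity, partial-volume mixtures at the tube wall, susceptibility
artifacts at the agarose-air interface, or cell-uptake kinetics. Passing
tests therefore demonstrate the correctness of the algorithmic chain
under controlled geometry and Rician noise — not robustness to scanner
physics the phantoms never contained.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use 64^3 scans for the
registration and pipeline studies (20 affine draws, 3 warp draws), 24^3
two-tube phantoms (~1700 voxels) for the T1 studies, and blobs up to 20^3
against the brute-force distance oracle — sizes at which every stage's
oracle can be recomputed from scratch in the same run. Other conventions:
voxel indexing is 0-based in the physical mapping
(`phys = origin + direction %*% (spacing * index)`), matching the DICOM
patient-coordinate convention and mapped losslessly to NIfTI; invalid
voxels are carried as an explicit mask (never magic numbers) and excluded
from every sum; Otsu ties resolve to the lowest cut; heap ties in the
distance transform resolve by voxel index; all randomness is seeded.

## Known limitations

* The elastic stage reports the minimal-deformation solution within the
  tube's symmetry group; tangential/azimuthal deformation components are
  unidentifiable on homogeneous tubes (see above) and are regularized to
  zero rather than estimated.
* The DICOM codec covers explicit-VR little-endian single-frame series —
  the geometry, rescale and timing tags this workflow needs — not
  compressed transfer syntaxes, enhanced multi-frame objects, or
  vendor-private formats.
* Reflectivity presumes the control mean is positive on the analysis
  mask; backgrounds with zero-mean noise should not be included in masks.
* T1 fitting assumes ideal saturation recovery; stimulated echoes, B1
  error and slice-profile effects in real fast spin-echo data would bias
  T1 in ways the phantoms do not represent.
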