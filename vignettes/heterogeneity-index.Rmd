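---
title: "The H index: a single-parameter measure of intratumor heterogeneity from FDG-PET SUV volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The H index: a single-parameter measure of intratumor heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetindex)
```

## The problem

Malignant tumors are metabolically heterogeneous, and the spatial pattern of
that heterogeneity — visible in ¹⁸F-FDG PET as voxel-to-voxel variation of the
standardized uptake value (SUV, g/ml) — correlates with prognosis and with
response to radiotherapy. Established texture approaches such as the
gray-level co-occurrence matrix (GLCM) summarize this variation with several
parameters of differing sensitivity, which complicates clinical use. This
package implements a *single* signed, dimensionless index, H, built directly
from differential SUV between neighbouring tumor voxels, alongside the
four-parameter GLCM benchmark it is compared against.

## The model

For a tumor of M voxels segmented from an SUV volume, let SUV_i be the uptake
of voxel i, N_i the number of tumor voxels adjacent to it under
26-connectivity (at most 26 in 3D, 8 on a single slice), and |ΔSUV|_ij the
absolute uptake difference between voxel i and its j-th in-mask neighbour.
The SUV-weighted tumor centre is

$$\mathbf r_c = \frac{\sum_i SUV_i\,\mathbf x_i}{\sum_i SUV_i},$$

with d_i the Euclidean distance of voxel i from r_c and d_max its maximum
over the tumor. The magnitude of the index is

$$|H| \;=\; \frac{1}{M}\sum_{i=1}^{M} \frac{d_i}{d_{max}}\;
\frac{1}{N_i}\sum_{j=1}^{N_i}\frac{|\Delta SUV|_{ij}}{SUV_{th}},$$

where SUV_th (default 2.5 g/ml, the conventional segmentation threshold)
makes H dimensionless. The weight d_i/d_max deliberately amplifies
heterogeneity sitting at the tumor periphery, the clinically adverse pattern.
The per-voxel average 1/N_i and the global 1/M keep H from growing trivially
with tumor size: "size-weighted" enters through the distance ratio, not
through raw volume. Voxels with no in-mask neighbour contribute 0; a
single-voxel tumor is defined to have H = 0 (no neighbour differences and no
distance scale), rather than raising an error.

The sign compares the volume-averaged SUV of the whole tumor with that of an
inner region, the tumor shrunk from the periphery toward the centre: voxels
with d_i ≤ ½·d_max. Whole mean ≤ inner mean (uptake descending from centre to
rim, ties included) gives +1; otherwise −1. "Shrunk by 1/2" admits several
readings — half the maximal radius (used here, the simplest consistent one),
half the volume, or a half-extent erosion — so the fraction is exposed as
`inner_fraction` (strictly between 0 and 1). The inner region is never empty:
the voxel at minimal d_i always qualifies.

Adjacency is defined on voxel indices (Chebyshev radius 1) and ignores
anisotropic spacing, keeping the neighbour count at the fixed "26 or less";
centroid distances, by contrast, default to physical millimetres
(`use_physical_spacing = TRUE`). Since w_i is a ratio, the unit cancels, and
with isotropic voxels the index-space option is identical.

## GLCM benchmark

`quantize_suv()` maps in-mask SUV to G gray levels (default G = 64,
equal-width bins over the in-mask min–max range — the dominant radiomics
convention; the binning used for the original patient analyses is not
published, so cross-study comparisons here are qualitative orderings, never
bar-height matches). `cooccurrence()` accumulates one count per *ordered*
in-mask neighbour pair over all 26 (or 8) unit offsets and normalizes to a
symmetric probability matrix P; pairs with one endpoint outside the mask are
discarded, so texture is strictly intratumoral. `glcm_features()` returns

* Energy = Σ P², Contrast = Σ (g−h)² P,
* Local Homogeneity = Σ P/(1+(g−h)²), Entropy = −Σ P log P (0·log 0 = 0),

with natural-log entropy by default (`entropy_base = "2"` for bits; no base
is canonical).

## Phantoms: what they emulate, and what they do not

The validation inputs are deterministic digital lesions. A large sphere of
radius r_max = 30 voxels carries the modified-Gaussian profile

$$SUV(d) = B + A e^{-d^2/R^2},$$

with A and B pinned so the centre reads 40 g/ml and the surface 2.0 g/ml;
R = 0 degenerates to the homogeneous 2.0 g/ml baseline. This offset-Gaussian
form is the minimal one satisfying both printed boundary values and is
isolated in `gaussian_sphere_profile()`. Sub-sphere assemblies embed N ≤ 4
small spheres of radius r_s at distance D from the host centre, placed
deterministically along +x, −x, +y, −y (maximally separated; the published
cross-sections do not parameterize placement). Each small sphere peaks at 40
at its own centre and decays with the same modified-Gaussian form — its size
parameter is taken equal to r_s, which is not specified anywhere — to the
host's SUV at its radial boundary point, so the blend is continuous. The host
sphere of the sub-sphere families uses R = 30, per the published phantom
descriptions. Background voxels default to 0 g/ml so threshold segmentation
at 2.5 recovers a sphere-interior mask.

Sweeps (`sweep_phantoms()`, `standard_sweep_specs()`) evaluate features on
the *geometric* sphere-interior mask rather than a threshold mask: the two
differ only in a thin sub-threshold surface shell (surface value 2.0 < 2.5),
and the geometric mask keeps the R = 0 baseline non-empty, which the
threshold cannot. The default grid is 80³ voxels — comfortably containing the
radius-30 sphere — and phantom generation involves no randomness, so every
sweep is bit-reproducible.

Six single-slice patterns (`build_pattern2d()`) provide 2D cases: a smooth
ramp and a checkerboard with mean SUV exactly 5 (the checkerboard strictly
more heterogeneous), a centre-peaked disk, concentric rings, constant
quadrants, and an ascending cone whose H is negative. The published 2D images
exist only as figures, so these are parameterized *analogs* reproducing every
stated constraint, not pixel reproductions; quantities that depend on the
original pixels (e.g. the printed 2.7× ratio between two of the patterns, or
the −0.017 value of the ascending one) are reproduced as properties — ratio
greater than 1, sign negative — not as numbers.

These phantoms emulate smooth, spherically symmetric lesions with noiseless
voxel values. They do not emulate PET count noise, reconstruction blur or
partial-volume effects, irregular lesion shapes, or anisotropic clinical
voxel grids; passing the phantom suite therefore demonstrates correctness of
the computations and the published orderings, not clinical performance on
patient data.

## Numerical choices and degenerate inputs

* Threshold segmentation is inclusive (SUV ≥ SUV_th), so a lesion whose
  minimum equals the threshold stays intact; whether the original clinical
  pipeline used ≥ or > is unknown.
* Empty masks are legal output of segmentation but rejected by every feature
  computation; an all-zero-SUV mask has no defined centroid and errors.
* d_max = 0 (single voxel) sets all weights to 0.
* Equal-width quantization maps a constant region to level 1; the top bin is
  right-closed so the maximum maps to level G.
* A mask with in-mask voxels but no in-mask adjacency has an undefined
  co-occurrence matrix and errors; `het_features()` reports the four texture
  features as NA in that case while still computing H.
* Sign ties take the + branch ("less than or equal").
* The optimized neighbour accumulation (one vectorized pass per offset) is
  checked against naive per-voxel, per-offset loops: exactly for integer
  co-occurrence counts, to 1e−10 relative for H.

## Problem sizes

The test suite validates the hand-worked examples on tiny grids, the
brute-force equivalences on 50 random volumes up to 8³, and the ordering
properties on the full 80³ sweep (14 phantoms); `scripts/acceptance.R`
re-runs the 80³ sweep, the 2D patterns, the checkerboard enumeration and a
25-volume brute-force cross-check. A full run of either takes well under a
minute on a single core.

## Worked example

```{r example}
spec <- phantom_spec("single_sphere", R = 12)
vol <- build_phantom(spec)
f <- het_features(vol, phantom_mask(spec), tumor_id = "R12")
summary(f)
coef(f)
```

## Limitations

H compresses heterogeneity into one number: different spatial patterns can
share an H value, and the GLCM quartet remains the richer (if less
interpretable) description. The index presumes SUV input — computing SUV from
raw DICOM activity, weight and timing fields, image registration and PET
reconstruction are out of scope. The published patient-level correlations
(e.g. H versus post-radiotherapy volume change) rest on undeposited clinical
data; `correlate_features()` ships the generic R² utility, not that analysis.
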