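---
title: "From breast MRI to dielectric phantom: methods and design notes"
author: "BreastPhantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From breast MRI to dielectric phantom: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BreastPhantom)
```

## The problem

Microwave breast imaging research needs anatomically realistic numerical
breast models: voxel grids in which every element carries a tissue label
and frequency-dependent dielectric properties. Such phantoms are
conventionally derived from breast MRI, because a fat-suppressed
acquisition shows the spatial distribution of the two tissues that
matter most at microwave frequencies — fat (low permittivity and loss)
and fibroglandular tissue (high permittivity and loss, and the usual
host of malignancies). BreastPhantom implements the full construction
chain: DICOM series in, segmented and property-assigned model out, in
STL / RAW / HDF5 / XML containers that electromagnetic solvers consume.

The emulated acquisition is a 3 T gradient-recalled-echo dual-echo
fat-suppressed breast protocol: 240 slices of 256 x 256 pixels at
0.9375 x 0.9375 x 1.1 mm voxels, TR 4.654 ms, dual TE 2.66/1.392 ms,
flip angle 10 degrees. Those values are the defaults of
`acquisitionMeta()` and `syntheticParams()`.

## Pipeline stages and their assumptions

`buildModel()` chains the stages below; each is exported and usable on
its own.

**Breast masking** (`buildBreastMask`). A background threshold is
estimated as mean + 3 sd of the corner-margin intensities (margin width
5% of each dimension) — the corners of a breast acquisition are air.
The volume is then traversed along the three orthogonal plane normals;
along every 1-D ray the region between the first and last run of at
least 3 consecutive above-threshold voxels is filled, and the three
per-axis regions are intersected. A final largest-connected-component
pass (6-connectivity, configurable to keep 2 components for bilateral
scans) removes stray blobs. The minimum run length of 3 rejects salt
noise; the per-ray fill closes interior gaps, which is this package's
reading of surface sensing along orthogonal planes. The threshold
estimator warns when fewer than 2% of voxels exceed the threshold —
the signature of object tissue occupying the corner margins, in which
case the margins were not background and the mask is unreliable.

**PCA denoising** (`pcaDenoise`). The volume is unfolded as a
slices-by-pixels matrix (slices as observations), centred, and
reconstructed from the leading principal components — by default the
smallest set reaching 99% of variance. Components shared across slices
are dominant anatomy; per-slice ripple (Gibbs ringing) and background
noise land in the weak components and are discarded. Negative
reconstructed intensities are clamped to zero.

A consequence of this unfolding, found during development and worth
stating plainly: low-rank reconstruction in a slice basis *ghosts*
faint copies of breast structure into background voxels of neighbouring
slices. A mask computed from the denoised volume therefore dilates
grossly along the slice axis (on a dense synthetic phantom the mask
absorbed roughly 0.9 million background voxels, which corrupted the
density estimate by ten percentage points). For that reason
`buildModel()` estimates the mask on the *original* intensities and
applies the denoised intensities only to segmentation inside the mask.
Both stages remain independently callable in any order.

**Segmentation** (`segmentTissues`, `subclusterFgt`). Skin is a
geometric shell: the mask voxels within `skin_thickness_mm` (default
1.5 mm, spacing-aware Euclidean distance) of the mask's exterior
surface. Skin intensity overlaps both fat and gland in this sequence,
so an intensity definition would be unstable; a geometric shell is
unambiguous and configurable. Grid faces flush with the volume boundary
(the chest wall) grow no skin. The remaining interior is split into fat
and fibroglandular classes by two-class k-means on intensity
(`stats::kmeans`, 10 restarts under a fixed seed); the brighter class
is fibroglandular under fat-suppressed contrast. Fat stays a single
cluster; the fibroglandular class can be re-partitioned into K
intensity clusters (`subclusterFgt`), relabelled in ascending order of
cluster mean, which tunes model heterogeneity without changing the
anatomy. A degenerate interior (fewer than two distinct intensities)
becomes a single fat class with a warning.

**Dielectric assignment** (`assignProperties`). Every model element
carries a single-pole Debye parameter set (eps_inf, delta_eps, tau,
sigma_s) evaluating to

eps*(w) = eps_inf + delta_eps / (1 + j w tau) + sigma_s / (j w eps0),

with the loss convention eps* = eps' − j eps'', eps'' >= 0. Skin, fat
and tumour take their reference parameters directly. Each
fibroglandular cluster is mapped linearly: its mean intensity becomes a
weight w = (mean − lower) / (upper − lower), clamped to [0, 1], over
the fibroglandular intensity range, and the lower/upper bounding curves
are combined componentwise as (1 − w) lower + w upper. Componentwise
combination keeps the result a valid single-pole Debye model — a
pointwise-in-frequency mixture of two Debye curves generally is not —
and matches the one-parameter-set-per-cluster property files the
package writes.

Three fibroglandular contrast levels are provided: high (scale 1.0),
med (0.85) and low (0.75). A level multiplies eps_inf, delta_eps and
sigma_s and leaves tau, which scales the entire complex spectrum by the
factor at every frequency — that identity is asserted in the test
suite to 1e-12. Whether the conductivity should also scale is genuinely
ambiguous in the field; scaling the whole complex curve is the literal
reading adopted here, and the operation is a single function
(`applyPropertyLevel`) that a user can replace.

The default reference table (`defaultPropertyTable()`, shipped as
`inst/extdata/default_properties.yaml`) holds representative
microwave-band Debye values for skin, fat, the fibroglandular bounds
and a malignant tumour. They are synthetic defaults chosen to be
physical (Re eps* >= 1, eps'' >= 0 over 0.5–10 GHz, asserted in tests)
and in the range used by numerical breast phantoms; quantitative work
should substitute a literature-derived table via `readPropertyTable()`.

**Classification** (`computeDensity`, `classifyBreast`). Breast density
is the fibroglandular percentage of the soft interior, 100 n_fgt /
(n_fat + n_fgt); skin, tumour and background are excluded (a flag
includes skin in the denominator). The four radiological classes map
onto density as fatty < 25, scattered [25, 50), heterogeneously dense
[50, 75), dense >= 75, with boundaries assigned upward because "less
than 25%" is strict.

**Tumour inclusion** (`generateTumour`, `embedTumour`). The default
inclusion is a 10 mm sphere voxelized on a 0.25 mm isotropic grid
(voxel centre inside the sphere), carrying the tumour reference
properties. Embedding snaps the requested centre to the nearest host
voxel and shifts the mask by whole voxels, so the inclusion is rigid;
it overwrites only fat and fibroglandular voxels — never skin or
background — and is rejected when its centre is outside the breast or
more than 10% of its volume would fall on non-soft tissue.

## The synthetic-data generator

`generateBreastVolume()` makes every stage testable without patient
data. It emulates the *statistical* structure of the acquisition, not
MR physics (no Bloch simulation, no coil sensitivity):

- a half-ellipsoid breast (default semi-axes 90 x 85 x 95 mm) resting
  its flat face on the chest-wall side of the grid;
- a geometric skin shell of `skin_thickness_mm`;
- fibroglandular structures from thresholding a smooth correlated
  random field (coarse Gaussian noise, lightly smoothed, trilinearly
  upsampled; correlation length default 12 mm). The threshold is the
  interior quantile matching `target_fgt_fraction`, which makes the
  achieved fraction exact to voxel resolution and monotone in the
  target — the properties the test oracles rely on;
- class intensities drawn from normal distributions (fat 60, gland 200,
  skin 120, sd 10/25/15, arbitrary units — the sequence's contrast
  ordering is what matters), background from folded noise (sd 5);
- in-plane Gibbs ringing by k-space truncation (70% kept per axis by
  default), because the real scans exhibit it and the pipeline is
  supposed to survive it;
- quantization to integers, like magnitude DICOM data.

The generator emits ground-truth labels and the true fibroglandular
fraction. What passing tests show is that the pipeline recovers
geometry and density under bimodal, ringing-corrupted, noisy contrast;
what they cannot show is performance under real-scan phenomena the
generator omits — coil shading and bias fields, motion, partial-volume
mixing at acquisition resolution, vasculature, and anatomy that is not
an ellipsoid. The generator can also write its volume as a DICOM
series (minimal explicit-VR little-endian tags) so the reader is
exercised end to end.

## Numerical choices and degenerate inputs

- Distances (skin shell, generator truth) use an exact anisotropic
  3-D Euclidean distance transform (separable lower-envelope algorithm,
  compiled); a large finite sentinel stands in for infinity so masks
  that touch no background remain well-defined (they report +Inf).
- k-means determinism: every clustering call seeds the RNG explicitly
  and restores the caller's RNG state; labels are relabelled by
  ascending cluster mean so the legend order is a contract, not an
  accident of initialization.
- Resampling is trilinear with border clamping; identical target
  spacing returns the input bit-for-bit.
- STL meshes are watertight voxel-face (cuberille) triangulations of
  the 0.5-level mask: two triangles per exposed voxel face, outward
  normals, millimetre coordinates. The enclosed volume equals voxel
  count times voxel volume exactly, which is the quantity simulators
  discretize anyway; the trade-off is a faceted rather than smoothed
  surface. No installed meshing library was used; the writer and a
  verifying reader are ~100 lines and tested against analytic cube and
  sphere volumes.
- DICOM support is deliberately minimal: single-frame, explicit-VR
  little-endian, monochrome 16-bit — the shape of the emulated series.
  Implicit-VR or compressed transfer syntaxes are rejected with a clear
  error rather than mis-read. Slice order comes from image positions
  (never file names); duplicate positions raise an "ambiguous ordering"
  error; positions win over a contradicting declared thickness with a
  warning.
- Voxel grids use (row, column, slice) index order, 1-based in R, with
  rows fastest in memory; the RAW writer documents this in its sidecar.

## Problem sizes used by the test suite

Unit tests run phantoms of 48 x 48 x 24 voxels at 2 mm (helper
default) and 96 x 96 x 64 at 2.5 mm where boundary effects matter:
at very coarse grids a realistic skin shell spans a third of the breast
and its segmentation leak dominates the density error, which stresses
the fixture rather than the method. The acceptance suite verifies the
default 256 x 256 x 240 acquisition geometry through the DICOM
round-trip once, and runs the density-recovery sweep (targets 0.10,
0.30, 0.60, 0.85, recovered within 3 percentage points) at
128 x 128 x 96 with 1.875 x 1.875 x 2.75 mm voxels — the default
physical extent at half resolution, where each full-pipeline run takes
seconds. Density errors shrink with finer grids (measured ~1 point at
192 x 192 x 160), so the half-resolution check is conservative.

## Known limitations

- Skin is geometric, not intensity-derived; its thickness is a
  parameter, not an estimate.
- Chest-wall and pectoral structures are not delineated; the mask ends
  at the grid face.
- Two-class intensity clustering has no spatial regularization; heavy
  noise produces salt-and-pepper labels that sub-clustering inherits.
- The Debye table ships representative defaults, not fitted literature
  curves; all quantitative dielectric claims in the tests are ratios
  and physicality bounds, never absolute values of the defaults.
- The 0.85/0.75 level factors scale the whole complex curve including
  conductivity; if a downstream convention scales permittivity only,
  replace `applyPropertyLevel`.
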