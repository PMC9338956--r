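---
title: "Methods: cell-body segmentation, morphometry and elastic registration for label-free cortical OCT"
author: "octcortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-body segmentation, morphometry and elastic registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octcortex)
```

## The imaging problem

Optical coherence tomography (OCT) of the rodent cortex through a chronic
cranial window resolves individual cells without any label: cell bodies
scatter less than the surrounding neuropil and appear as *circular dark
foci* in en-face slices, while myelinated axons scatter strongly and appear
as *bright filaments*, mostly where they run parallel to the imaging plane.
Blood vessels are dark tubes that, viewed en face, masquerade as cells.
The tissue is organized in cytoarchitectonic layers (I–V) whose typical
soma size differs — a fact the segmentation exploits by matching its kernel
to the layer.

`octcortex` implements the computational side of such a study: a
matched-filter cell-body segmentation with 3D morphological acceptance
rules, an oriented-kernel filament segmentation, depth-blocked morphometry,
and longitudinal rigid-then-elastic registration of cell centroids that
yields a cortical "elasticity map". A phantom generator with exact ground
truth makes every stage testable at desk scale.

## Cell-body segmentation

The detector is a single convolution layer followed by a threshold and
morphological rules:

1. **Convolution.** Each en-face slice is inverted (`max − I`, because the
   targets are dark) and convolved with a uniform circular kernel of the
   layer's expected soma diameter — 8 µm for layers II–IV, 13 µm for
   layer V. Weights sum to one, so the response is a local mean and is
   comparable across kernel sizes. The border is handled by mirror
   reflection. Disk membership uses the pixel-center radius
   `(d_px − 1)/2`, so a diameter-`d` disk spans `d` pixels across when `d`
   is odd and the footprint is always odd-sized (a 3-px disk is the
   5-pixel cross).
2. **Per-slice percentile threshold.** Within each slice the top 0.5 % of
   response pixels become candidates (the 99.5-th percentile, interpolated;
   candidates are strictly above it, so ties at the threshold are
   excluded and the rule is deterministic). The threshold is per slice,
   not per volume, which makes detection robust to depth-dependent signal
   falloff.
3. **3D morphological rules.** Candidates are grouped into 26-connected 3D
   components. With `D` the layer's kernel diameter, a component is kept
   iff
   * (a) it appears in at least 3 consecutive axial slices *and* spans at
     least 4 µm of depth,
   * (b) its volume does not exceed the volume of the diameter-`D` sphere,
     `(4/3)π(D/2)³`, and
   * (c) its axial spread does not exceed `2D`.
   Rule (c) is what rejects blood vessels: a vertical tube of cell-like
   width fails it decisively. A stricter upper bound on (a) — axial spread
   at most one diameter — is counted and reported, and can be made the
   hard gate via `segmentation_params(axial_gate = "diameter")`.

**Why the sphere bound references the kernel diameter.** The acceptance
rules compare each component against the *expected* cell of its stratum,
which is exactly what the layer-matched kernel encodes. The alternative —
bounding a component's volume by the sphere of its own maximal
cross-section — is self-referential and interacts badly with the fixed
percentile budget: when cells occupy a larger area fraction of a slice
than 0.5 %, the threshold captures only each cell's core, and a core
column always exceeds the sphere of its own small cross-section, so
essentially every true cell would be rejected. Tying the bound to the
kernel keeps the rules meaningful across detection regimes, at the cost of
making `D` an explicit model parameter (which it already is for the
convolution).

**The threshold–density coupling.** Because the percentile fixes the
candidate *budget* per slice, detection quality depends on how the true
cell area fraction compares with 0.5 %: much denser tissue gets only cell
cores (volumes are then under-estimated), much sparser tissue hands the
surplus budget to speckle peaks (which the axial rules mostly absorb) and
slightly over-segments each cell. This is a property of the method, not of
the implementation, and is the reason recovered mean cell volumes carry a
partial-volume/threshold bias of up to ~25 % depending on density.

Cells straddling a layer-band boundary are detected intact (each band is
processed with a margin of extra slices, `band_margin_um`) and report to
the band containing their centroid; exact boundary ties go to the
shallower band.

### Filament segmentation

Bright filaments are detected per slice with the same percentile machinery
under *bright* polarity, replacing the disk with four 1-px-thick uniform
line kernels (horizontal, vertical, both diagonals; default length twice
the 8 µm cell kernel) combined by per-pixel maximum, so a segment at any
of the four canonical orientations scores highly. No 3D sphere or axial
rules apply — filaments are elongated by nature. The output is a boolean
mask; only in-plane filaments are expected to be visible, matching how
OCT reveals myelinated processes.

## Morphometry

From the accepted cell table the package reports, in depth blocks of
27 µm (tiled, anchored at the top of the analyzed range; the last partial
block keeps its true thickness):

* **density** — centroid count divided by the block's physical volume, in
  cells/mm³;
* **mean cell-body volume** — arithmetic mean of per-cell voxel volumes;
* **mean nearest-neighbor distance** — per-cell 3D Euclidean distance to
  the nearest *other* cell; the neighbor search is never restricted by
  block or layer boundaries, since physical distance is block-agnostic.

Exact boundary ties go to the shallower block, mirroring the layer rule.

## Longitudinal registration

Sessions of the same field of view are aligned in three stages:

1. **Coarse, vessel-based.** Mean-intensity en-face projections (dominated
   by the dark vessel pattern) are aligned by FFT cross-correlation for
   translation, with an exhaustive in-plane rotation search over ±10° at
   0.5° steps; the 2D result is embedded as a 3D transform with no
   out-of-plane component (the projection carries none; depth is left to
   ICP). A normalized correlation floor guards against non-overlapping
   inputs.
2. **Rigid ICP on centroids.** Nearest-neighbor correspondences under a
   hard 10 µm gate (registered cells are assumed less than 10 µm apart),
   closed-form orthogonal Procrustes update, iterated until the mean gated
   distance improves by < 1e-3 µm (cap 50 iterations). An update is
   accepted only if it improves the gated mean distance, so the recorded
   trace is monotonically non-increasing even though gating can otherwise
   cause small oscillations.
3. **Block-wise elastic ICP.** The volume is tiled into 50 µm-edge cubes.
   (The natural reading of a "50 µm" sub-volume: a cube of 50 µm³ volume
   would be ~3.7 µm across and could never hold more than 10 cells.)
   Blocks holding **more than 10** rigidly-aligned moving cells are
   re-registered independently by gated ICP; all other blocks inherit the
   rigid transform verbatim. The per-block residual displacements at block
   centers are then smoothed by fitting one global second-order polynomial
   per displacement component (10 coefficients each, least squares,
   degrading to linear or constant when too few blocks qualify). A global
   quadratic is the simplest model that matches "quadratic smoothing",
   guarantees a continuous field, and cannot oscillate between blocks;
   a spline alternative would add boundary-condition choices without a
   criterion to set them.

**Matching and the elasticity map.** Cells are matched one-to-one across
sessions by mutual nearest neighbors under the 10 µm gate after applying
the field; the matched fraction of fixed cells and signed per-axis offset
histograms (0.5 µm bins over ±10 µm) are reported. The elasticity map is,
per cell, the delta between elastic and rigid registration — where the
local deformation moved the cell beyond the global rigid motion — rendered
as arrows colored by direction with length equal to magnitude. When several
sessions exist, all are registered to a common reference session (the
middle one in a three-session design).

## The phantom generator

The generator emulates the *appearance-level* features the algorithms key
on, with exactly known geometry:

* **cells**: anti-aliased (1-voxel linear partial-volume edge) spheres,
  multiplicative intensity dip `contrast` (default 0.5 — the printed
  figures show roughly half-background somata, and contrast is swept in
  tests); diameters N(8, 0.5²) µm in layers II–IV and N(13, 0.8²) µm in
  layer V; centers placed by rejection sampling with a minimum separation
  of 1.5× the mean diameter so recall and PPV are well defined;
* **densities**: 8×10⁴ cells/mm³ in layers II–IV — the order reported for
  mouse cortex — and 4×10⁴ in layer V, which is cytoarchitectonically
  sparser and, with 13 µm somata, could not physically pack at the higher
  figure under the separation constraint;
* **vessels**: dark tubes (axis-aligned or arbitrary direction);
  **filaments**: thin bright in-plane tubes at the four canonical
  orientations;
* **speckle**: per-voxel multiplicative unit-mean gamma noise
  (`shape = 20` by default), the standard fully-developed-speckle
  approximation; the volume mean equals the structural mean to within 1 %
  at 10⁶ voxels;
* **session pairs**: session 2 re-renders the same cells at
  `rigid(p + u(p))` with `u` a smooth analytic (quadratic) displacement
  field, under fresh speckle; vessels and filaments follow the rigid
  motion (they anchor the coarse registration), while the few-µm elastic
  field moves cells only. Displacements larger than half the minimum cell
  separation are refused — correspondence would be ambiguous.

What the phantom does **not** model: the confocal point-spread function,
depth attenuation, refraction, motion artifacts, or any biological
heterogeneity of scattering. Passing the phantom suite therefore
demonstrates algorithmic correctness under the stated noise model, not
in-vivo performance; real cortical volumes are harder than any phantom
here, and reported in-vivo sensitivities for this class of detector are
substantially lower than phantom recall.

Voxels default to 1 µm isotropic. The axial sampling of a real system may
be coarser (an axial step of 4/3–2 µm makes "3 consecutive slices" equal
the 4 µm depth minimum); `dz` is therefore configurable everywhere and the
acceptance rules apply both the slice-count and the physical-depth gate
separately, so they remain correct at any `dz`.

## Numerical choices

* Percentile: R's interpolated type-7 quantile; candidates strictly above
  it. On continuous-valued slices the candidate count equals the 0.5 %
  budget to within one pixel (audited exactly in the tests).
* Connectivity: 26-neighborhood, so diagonal speckle fragmentation does
  not split small somata; exposed in `segmentation_params()`.
* Convolution border: mirror reflection; the labeling and centroid code
  works in physical µm with voxel centers at `(i − 1)·spacing`.
* Whole-voxel translation equivariance holds to a fraction of a voxel
  (not exactly): the per-slice threshold couples all pixels of a slice
  through the border reflection, so shifting content perturbs the
  threshold by a vanishing amount.
* ICP tie-breaks: nearest fixed point per moving point; no trimming beyond
  the hard gate; Kabsch/SVD solution with determinant correction.
* Degenerate inputs: constant slices yield no candidates (with a warning);
  fewer than 2 cells make the NN distance `NA`; fewer than 3 gated ICP
  matches abort with a divergence error; an elastic run in which no block
  qualifies returns the rigid-only field with a warning.

## Problem sizes used by the test and acceptance suites

Unit tests run on phantoms of roughly 40–150 µm extent (seconds each). The
acceptance suite exercises five seeded 200×200×160 µm two-band phantoms
(~400 cells each), one full-size 350×350×300 µm volume (~2 450 cells,
segmented in about a minute on one CPU), registration point sets of
300–4 000 cells, and a longitudinal pair segmented end-to-end. These sizes
were chosen to keep the full suite in the minutes range while leaving every
stated operating condition (kernel sizes, contrast, speckle shape, cell
counts ≥ 200, gates) intact.

## Known limitations

* The detector cannot distinguish neurons from glia — nothing in the
  contrast mechanism separates them.
* Sensitivity is bounded by the percentile budget whenever the true cell
  area fraction exceeds 0.5 % per slice (see the threshold–density
  coupling above).
* The elastic model is a single global quadratic; deformations with
  higher spatial frequency than one bend across the volume are smoothed
  away.
* Coarse registration assumes the vessel pattern dominates the en-face
  projection and that out-of-plane rotation is negligible over a session.
* The filament mask is boolean and unlabeled; no tracing or connectivity
  analysis is attempted.
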