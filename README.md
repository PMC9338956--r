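# octcortex

Label-free OCT neuroimaging of the cortex resolves single cells without any
stain: cell bodies appear as circular dark foci in en-face slices, and
myelinated axons as bright filaments. `octcortex` is an R implementation of
the computational stack such a study needs — for imaging labs that want to
quantify cortical cytoarchitecture and its slow temporal dynamics from 3D
OCT volumes:

* **cell-body segmentation** — per-slice convolution with a layer-matched
  circular kernel (8 µm for cortical layers II–IV, 13 µm for layer V), a
  per-slice 99.5 % response threshold, and 3D morphological acceptance
  rules that reject blood vessels;
* **filament segmentation** — four oriented line kernels (0°, 45°, 90°,
  135°) under bright polarity;
* **morphometry** — cell density, mean cell-body volume and mean
  nearest-neighbor distance in 27 µm depth blocks;
* **longitudinal registration** — coarse vessel-based en-face alignment,
  rigid ICP on cell centroids with a 10 µm gate, block-wise elastic ICP
  (50 µm cubes, only blocks holding > 10 cells) with quadratic smoothing,
  mutual-nearest-neighbor cell matching, and the resulting cortical
  **elasticity map** (per-cell elastic-minus-rigid deltas);
* **a phantom generator** — spherical dark cells, tubular vessels, bright
  filaments, multiplicative unit-mean gamma speckle and analytic
  inter-session deformations, with exact ground truth, so the entire
  pipeline is testable without any data download.

## The core algorithm

For each en-face slice *I* at depth *z* and a layer with expected soma
diameter *D*:

1. response *R* = (max *I* − *I*) ∗ *K_D*, where *K_D* is a uniform disk of
   diameter *D* (weights sum to 1, mirror-reflected border);
2. candidates = { pixels with *R* strictly above the slice's 99.5-th
   percentile };
3. candidates are grouped into 26-connected 3D components; a component is a
   cell body iff it (a) appears in ≥ 3 consecutive axial slices spanning
   ≥ 4 µm, (b) has volume ≤ (4/3)π(*D*/2)³, and (c) has axial spread
   ≤ 2*D* — rule (c) is what excludes vessels.

Longitudinal alignment solves min Σ‖*R* pᵢ + *t* − qⱼ(ᵢ)‖² by gated ICP
(closed-form Procrustes updates), then refines per 50 µm block and smooths
the per-block residuals with one global second-order polynomial per
displacement component.

## Worked example

```r
library(octcortex)

cfg <- phantom_config(seed = 42)          # 200 x 200 x 160 um, two bands
ph  <- generate_phantom(cfg)
ph$volume
#> <oct_volume> 200 x 200 x 160 voxels (y, x, z), spacing (1, 1, 1) um,
#>   depth 100-259 um below window; intensity range [16.6, 262]

bands <- layer_bands(layer = c("II-IV", "V"),
                     depth_min = c(100, 180), depth_max = c(180, 260),
                     kernel_um = c(8, 13), excluded = c(FALSE, FALSE))
mask <- segment_cells(ph$volume, bands)
mask
#> <cell_mask> 381 accepted cell bodies (rejected: 1089 axial-min, 0 volume, 0 axial-max)

evaluate_detection(mask$cells, ph$truth$cells, match_radius_um = 5)
#> <eval_report> PPV 1.000, recall 0.953, centroid RMSE 0.56 um (381/381 detected, 400 truth)

morphometry_report(mask, lateral_um = c(200, 200), bands = bands)
#> <morphometry_report> 381 cells; mean volume 77.1 um^3; mean NN distance 17.37 um
#>   6 depth blocks:
#>  depth_min depth_max thickness_um n_cells density_mm3 mean_nn_um mean_volume_um3
#>        100       127           27      75       69444      15.96           63.05
#>        127       154           27     101       93519      15.16           52.69
#>        ...
```

Reading the output: of 400 seeded cells the detector reports 381, all of
them true (PPV 1.0 — matched detections over all detections), missing ~5 %
(recall 0.953), with centroids off by ~0.6 µm RMS. The per-block table
shows the depth profile of density (cells/mm³), nearest-neighbor spacing
and mean recovered volume; recovered volumes sit below the true sphere
volume because the fixed percentile budget captures cell cores plus a
partial-volume edge (see the methods vignette).

The rejection counters narrate the morphological filter: 1089 candidate
components (speckle fragments) fell below the 3-slice / 4 µm axial
minimum, none violated the sphere-volume or axial-spread rules in this
run.

For a longitudinal pair, `make_session_pair()` applies a known rigid +
quadratic motion, and

```r
rig   <- icp_rigid(cells_t1, cells_t0, gate_um = 10)
field <- elastic_register(cells_t1, cells_t0, rig)
match_cells(cells_t1, cells_t0, field, gate_um = 10)
```

recovers it to sub-µm accuracy; `elasticity_map()` and
`displacement_histograms()` reproduce the elasticity-map arrows and the
per-axis offset histograms.

A thin command-line wrapper lives at `inst/scripts/oct-pipeline.R`
(subcommands `run`, `phantom`, `segment`, `register`) driven by a single
YAML config; `run_pipeline()` is the same entry point from R and writes
masks, cell tables, morphometry, transforms, matches and a manifest with
parameters, seed and checksums.

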