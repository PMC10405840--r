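---
title: "Methods: phantom-validated quantification of FUS blood-brain-barrier opening readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated quantification of FUS blood-brain-barrier opening readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoquant)
```

Focused-ultrasound (FUS) blood-brain-barrier (BBB) opening studies quantify
their outcomes on images: the opening itself as a gadolinium-hyperintense
region on contrast-enhanced T1 MRI, tau pathology as the length of
HT7-positive neuronal processes on confocal sections, amyloid burden as
plaque population and volume on the Aβ channel, and clinical amyloid load as
the PET standardized uptake value ratio (SUVr).  `sonoquant` implements these
four measurement pipelines and a phantom generator that produces inputs with
exact ground truth, so every stage can be validated end to end without any
study data.

This vignette explains the models behind each stage, the tunable parameters
and their defaults, what the phantoms do and do not emulate, and the
numerical choices made where the methodology left room.

## MR opening volumetry

**Model.** The opening appears as a compact hyperintense region on a roughly
uniform background.  The volume is normalized by the mean intensity of an
"out-of-focus" reference box (`normalize_volume()`), putting the background
near 1 and cancelling any global intensity scale — the measured volume is
provably invariant under `I -> cI`, `c > 0`.  Each analysed slice is then
segmented with a region-based active contour (`segment_opening()`) and the
volume is the sum of per-slice areas times the slice thickness
(`opening_volume()`).

**Active-contour flavour.** We use a morphological two-phase region
competition of the Chan–Vese type: at every sweep the mean intensity inside
(`c1`) and outside (`c2`) the current region is recomputed, each pixel moves
to the side whose mean it is closer to, and a 3×3 majority vote regularises
the boundary, playing the role of the curvature term.  This variant needs no
PDE time step, converges in tens of sweeps, and on a sharp-edged region
reproduces the intensity bi-partition exactly.  `max_iter` (default 40)
bounds the sweeps; oscillating boundary pixels at lattice corners make exact
fixed points rare, and the bound costs well under a pixel of boundary error.

**Initialisation.** Contours start from the supra-threshold component of the
slice: pixels above `init_threshold` (default 1.3, i.e. 30% above the
normalized background; it must exceed 1 to mean anything after
normalization), cleaned by a minimum-component-size filter (`min_component`,
default 5 px).  The filter is what keeps pure-background slices empty under
noise: isolated supra-threshold noise voxels would otherwise seed a contour
that locks onto the upper noise tail.  Slices whose cleaned initialisation is
empty yield empty masks, and the default analysis slab is exactly the slices
where the component survives; a fixed slab (e.g. a 17-slice acquisition
convention) can be passed explicitly via `slab`.

**Accuracy.** On a noise-free rasterized sphere of radius 2.3945 mm at
0.05 mm isotropic spacing the pipeline recovers the analytic
\((4/3)\pi r^3 = 57.5\ \mathrm{mm^3}\) within 0.1%; the rasterization itself
bounds the achievable accuracy (the voxel-count volume differs from the
analytic one by under 1% at this spacing, and the tests assert both).

## Tau process morphometry (the structural algorithm)

The length of tau-affected processes is measured per cell:

1. **Mask** (`build_hippocampal_mask()`): an explicit polygon when given;
   otherwise Otsu on the nuclei channel, closed and hole-filled.
2. **Segmentation** (`segment_tau()`): k-means on masked pixel intensities
   with `k = 3` (default), keeping the cluster with the largest mean.  The
   method needs only "brightest structures stand out"; `k = 3` separates
   background, diffuse tissue signal and the tau-positive structures.
   Initial centres sit at fixed intensity quantiles, so the clustering is
   deterministic.  Fewer than `k` distinct levels is degenerate; the
   function falls back to thresholding at the top level and warns.
3. **Soma detection** (`detect_cell_centers()`): circular Hough voting over
   `radius_range` (default 5–12 px at 20× magnification scales); boundary
   pixels vote on annuli, the accumulator is normalized so a full circle
   scores 1, and `accum_threshold = 0.5` tolerates the perimeter lost to
   attached processes.  Peaks closer than the minimum radius are merged.
4. **Skeletonization** (`skeletonize_processes()`): morphological closing
   (radius 2 px) bridges staining gaps, then Zhang–Suen thinning reduces the
   segmented structures to a 1-px backbone whose degree-1 pixels are the
   endpoints and degree-≥3 pixels the branch points.
5. **Tracing** (`trace_processes()`): from the skeleton node nearest the
   detected centre (within `neighborhood_radius`, default 1.5× the largest
   detected soma radius), geodesic distances along the 8-connected skeleton
   reach every endpoint.  Axial steps weigh `pixel_size`, diagonal steps
   `sqrt(2) * pixel_size`; the geodesic (not the Euclidean chord) is used
   because chords under-report curved processes.  Endpoints reachable from
   several somata belong to the geodesically nearest one, ties to the
   smaller centre index — a deterministic rule.
6. **Per-cell statistic**: the mean of the `ceiling(0.05 n)` longest paths
   (minimum one), the "longest 5%" rule that makes the statistic a measure
   of how far pathology extends rather than of branching density.

Path lengths follow the soma-centre-to-endpoint convention: the trace starts
at the centre and the soma radius is *not* subtracted.  The phantom ground
truth records lengths under the same convention (the generator stores both
the drawn polyline length and the centre-to-endpoint length), so measured and
true lengths are directly comparable.  On rendered straight processes the
pipeline recovers lengths within ±2 μm at 1 μm/px: thinning erodes roughly
one pixel where the process cap meets its endpoint, the dilated rendering
adds one, and the start node sits within a pixel or two of the true centre.

**Group comparison.** Per group, the per-cell statistics form an empirical
CDF (`length_cdf()`).  Quantiles use the type-1 (inverse-CDF) convention —
the smallest sample value `v` with `F(v) >= q` — so "95% probability to find
a process equal or smaller than the 95th-percentile length" is literally true
on the sample.  `mc_difference_cdf()` draws `n_mc` (default 10^5) independent
pairs from the two empirical distributions (resampling with replacement; no
kernel density estimate is interposed, to keep the estimator free of
bandwidth choices), subtracts them, and reports the CDF of the differences;
its value just below zero is the probability that a group-A process is
shorter than a group-B process.  With `n_mc = 10^5` the Monte-Carlo standard
error of that probability is about 0.0014, comfortably inside the ±0.005 the
tests assert against exact enumeration.

## Amyloid plaque quantification

The amyloid channel is normalized by an out-of-focus box
(`normalize_channel()`), binarized at a **fixed threshold** (default 2.0 ×
background — held constant across an analysis, and recorded in every report
so a re-analysis can audit it), and connected components of at least
`min_size` px² (default 20, which suppresses noise specks that would inflate
the population) become plaque records (`detect_plaques()`).  Each plaque gets
its pixel-count area, the equivalent in-plane radius \(r = \sqrt{A/\pi}\),
and a volume extrapolated as the sphere \((4/3)\pi r^3\); an `area ×
section-thickness` slab model is available via `volume_model = "slab"`.
Touching plaques are not split — well-separatedness (≥ 2 px of background) is
a documented validity condition checked by the phantom generator, not a
watershed problem this package tries to solve.

Group statistics (`plaque_group_stats()`) report population and total volume
per group and the percent decreases `100 (1 - A/B)` of the comparison group
against the reference group.

Pixel-count areas of rasterized disks carry lattice error: for disks at
generic (non-lattice) positions the sphere-extrapolated volume is within
about 1% of the formula on average for radii ≥ 8 px, but particular
alignments (a centre exactly on a pixel or half-pixel) can deviate by several
percent.  The phantom generator therefore places disk centres at golden-ratio
sub-pixel offsets — real objects never sit exactly on the lattice — and the
accuracy tests assert the mean over placements.

## PET SUVr

`compute_suvr()` is deliberately minimal: given a PET volume and a
co-registered integer label volume, SUVr is the unweighted voxel-mean uptake
of the target region divided by that of the reference region (one or several
labels pooled, the "whole cerebellum" role).  Spatial normalization, atlas
segmentation and partial-volume correction are published, validated tools
and are out of scope; this module's contract starts after them.
`suvr_change()` reports `100 (followup/baseline - 1)`; reductions are
negative.  Whether a lobe-level SUVr should be the voxel mean or a mean of
sub-region SUVrs is ambiguous in general; the voxel mean is implemented
(pass pooled sub-region labels as `reference_ids`/`roi_id` groupings to get
the other reading region by region).

## Statistics and reporting

`two_group_t()` wraps the classical pooled-variance Student t (the default
of the statistics packages such studies use), `regress()` ordinary least
squares with the F test for a non-zero slope.  `assemble_report()` serializes
any subset of stage outputs with the full configuration, seeds and package
version, and contains no timestamps: re-running from the same config and
seeds produces byte-identical JSON, which the tests assert.  Multi-endpoint
corrections (Holm–Šídák and friends) are intentionally not applied by
default; single-endpoint runs mirror per-figure tests, and correction belongs
to the caller who knows the endpoint family.

## What the phantoms emulate — and what they do not

The phantoms are intensity-level objects with exact geometric ground truth:

* **MR**: one ellipsoidal hyperintense region on a uniform background plus a
  disjoint reference box; additive Gaussian noise clipped at zero.  The
  analytic \((4/3)\pi abc\) volume travels with the output.
* **Confocal**: filled somata with polyline processes drawn 1 px wide and
  dilated to 3 px (1-px lines are already skeletons; 3 px makes the thinning
  step do real work), disk plaques, scattered nuclei, per-channel gain and
  noise.  A fixed seed gives a bit-identical field, and the seed affects
  noise only — geometry is fully determined by the spec (nuclei scattering
  takes its own seed as part of the geometry description).
* **PET**: label-constant uptake per region and timepoint, so the true SUVr
  is exact by construction in the noise-free case.

They are *not* physical simulations: no k-space sampling, no point-spread
function, no scatter, no autofluorescence, no partial-volume effects, no
anisotropic staining.  Optional blur or background structure can be layered
on by the caller, but the defaults stay clean because the phantoms' job is to
validate the measurement chain against known truth, not to imitate scanner
physics.  Passing tests on phantoms therefore demonstrates correctness of
the algorithms under their stated validity conditions (separated plaques,
resolvable somata, sufficient contrast), not robustness to every artefact of
real acquisitions.

## Problem sizes and runtime choices

The validation suite runs at the sizes the phantoms need and no larger: the
sphere-recovery volumetry uses a 120×120×112 grid at 0.05 mm (1.6 M voxels);
the tau readout phantoms render 21 cells with processes up to 1400 μm at
1 μm/px (about 1.4 M px per field); plaque counting sweeps up to 200 disks;
the Monte-Carlo comparison uses 10^5 draws.  These sizes keep a full
end-to-end validation in the low minutes on one CPU while leaving every
ground-truth recovery well inside its stated tolerance.

## Known limitations

* The tracer is 2D, matching maximum-intensity-projection analysis; z-stacks
  must be projected first.
* Somata are assumed roughly circular for the Hough step; elongated or
  clustered somata can merge or split detections.
* Plaques touching within 2 px are counted as one; the generator enforces
  the separability condition rather than the detector resolving it.
* Per-process measurement error is ±2 μm at 1 μm/px, dominated by
  rasterization at the process end and the skeleton's approach to the soma
  centre; sub-pixel accuracy is out of scope.
* The fixed plaque threshold and the MR initialisation threshold are
  analysis parameters, not estimated quantities; both are exposed in the
  configuration and recorded in reports precisely because reasonable studies
  may set them differently.
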