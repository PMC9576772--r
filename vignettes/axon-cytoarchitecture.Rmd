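---
title: "Quantifying and regenerating white-matter axon cytoarchitecture"
author: "axoncyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and regenerating white-matter axon cytoarchitecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoncyto)
```

## The problem

White matter is, mechanically, a fibre composite: myelinated axons —
approximately parallel, slightly tortuous tubes with elliptical
cross-sections — embedded in a much softer extra-cellular matrix.
Micromechanical and fluid-dynamic models of the tissue (tissue
deformation, convection-enhanced drug delivery) need quantitative
geometry at the scale of individual axons: cross-sectional area and
best-fit diameter distributions, ellipticity, tortuosity, axonal
density and volume fraction, per fibre tract.

Serial FIB-SEM imaging provides that geometry: the microscope mills
~150 nm slices and images each face at ~0.020 um/pixel, yielding
anisotropic 3D stacks of roughly 15 x 15 x 15 um from which individual
axons can be segmented. This package implements the downstream
computational workflow:

1. **2D myelin content** (`quantifyMyelin()`): how much of an image is
   myelin, used to check that myelination is homogeneous across
   sampled locations.
2. **3D morphometry** (`measureVolume()`): per-axon centerlines and
   cross-sections measured on planes *perpendicular to each axon*,
   which removes the slice-angle distortion.
3. **Population statistics** (`fitLognormal()` and friends): the
   measured quantities follow lognormal distributions; tracts are
   summarised by the fitted log-scale parameters and the derived mode
   and median.
4. **In silico volume generation** (`generateRVE()`): periodic
   Representative Volume Elements (RVEs) of non-overlapping elliptical
   tubes whose statistics match a tract summary, exportable as
   watertight STL meshes for simulation.
5. **Synthetic phantoms** (`generatePhantomImage()`,
   `generatePhantomVolume()`): image- and volume-level simulators with
   exact ground truth, so every stage above is testable end to end
   without microscope data.

## The 2D myelin pipeline

Osmium-stained myelin appears as bright rings on a darker background.
The pipeline composes, in fixed order: a 3x3 median filter (mirror
padding; exact medians via a sorting network), a small morphological
opening (radius 1 px — isolated white pixels are not representative of
myelin), background estimation by greyscale opening with a large disk,
background subtraction (clamped at zero), adaptive binarisation, a
final small binary opening, and the white-pixel relative frequency
(white / total pixels).

Tunable parameters, with defaults:

* `backgroundRadius = 50` px (1 um at 0.020 um/px). The opening disk
  must exceed the largest axon radius so that the entire bright
  foreground is erased and only the smooth uneven illumination
  survives; 1 um sits above the largest tract-level best-fit
  diameters.
* `window`: adaptive-threshold window, 1/8 of the smaller image
  dimension rounded up to odd — a few ring diameters, so the local
  mean tracks regional brightness without following individual rings.
* `sensitivity = 0.9`, `offset = 0.05`. The threshold is
  `T = localMean * (2 - sensitivity) + offset` and a pixel is white iff
  it strictly exceeds `T` (ties black, a deterministic convention).
  The published description of this stage names only the behaviour
  ("locally computed thresholds"), not a formula, so the numeric
  defaults are meaningful only relative to this form. They were
  calibrated once on phantom round-trips: across truth fractions
  0.2–0.5 with impulse noise and illumination gradients the mean
  absolute recovery error is ~0.001 (sensitivity 0.5 under this form
  under-segments dense myelin by up to 0.1). The offset is a noise
  floor: after background subtraction the background is near zero, and
  a pure relative threshold would chase residual noise there.

What passing the phantom round trip does and does not show: the
phantoms contain annular rings, glial blobs, impulse noise, Gaussian
texture and low-order illumination fields — the failure modes the
pipeline stages are built for. They do not emulate myelin
delamination, curtaining or charging artefacts of real FIB-SEM
acquisitions, nor the partial-volume grey levels of real membranes;
accuracy on real stacks therefore rests on the adequacy of these
stages, not on the phantom numbers.

## 3D morphometry on perpendicular planes

Measurements taken on the imaging plane overestimate cross-sections of
any axon inclined by an angle alpha to the stack axis (area scales as
1/cos alpha). The package therefore measures on planes perpendicular
to each axon's centerline:

* **Centerline**: the chain of per-slice centroids, smoothed with a
  centred moving average over 5 stations. The proprietary tool used in
  the original workflow is not reproducible; the centroid chain is,
  and it is exact for tubular geometry at this tortuosity regime. For
  periodic volumes centroids are circular means, unwrapped across
  slices.
* **Stations** every 150 nm of arc length (the slice spacing), with
  half a spacing trimmed at each end (tangents there are one-sided)
  and tangents by central differencing.
* **Cross-sections**: the axon surface is the 0.5 iso-level of the
  trilinearly interpolated binary mask in physical micrometre
  coordinates — anisotropic voxels are handled by never resampling,
  only by interpolating in um space. The perpendicular plane is
  sampled on a grid at the in-plane voxel pitch and contoured at 0.5;
  if a station cuts several contours (touching axons after
  voxelisation) the one containing the centerline point is kept and
  the station flagged. Stations whose tilted plane would leave the
  z-extent of the stack, or whose section falls below the resolvable
  minimum (outer diameter 0.2 um), are skipped and counted.
* **Descriptors**: shoelace area; best-fit diameter
  `2*sqrt(area/pi)` (the equal-area circle — the original tool's
  definition is not published); moment-based ellipse fit (semi-axes
  from the second central moments of the polygon interior, rotation
  invariant); ellipticity `E = a/b - 1` (0 = circle, 1 = major axis
  twice the minor; the published anchors fix both points);
  tortuosity `tau = 1 - chord/arc` (0 = straight; the printed formula
  with the ratio inverted is negative for every curve, so the
  orientation that reproduces the printed positive means is used);
  axonal density (count over scanned volume, no edge correction);
  volume fraction (labelled voxels over all voxels).

The perpendicular-plane construction is verified against analytic
cylinders: at tilts up to 45 degrees the perpendicular section stays
within 2% of `pi r^2` while the imaging-plane section grows as
`1/cos(alpha)` — the defining oracle of the measurement stage (run at
isotropic 0.02 um voxels so the interpolation is equally resolved in
every direction; the anisotropic case is covered by the phantom round
trips).

## Lognormal population statistics

Cross-sectional areas, best-fit diameters and tortuosity are
well-described by lognormals. `fitLognormal()` is the closed-form MLE
(`mu = mean(log x)`, `sigma` with divisor n) with the derived
descriptors mode `exp(mu - sigma^2)`, median `exp(mu)`, arithmetic
mean and SD. `momentConsistency()` implements the agreement criterion
used for the published fits: the fit-implied arithmetic moments must
agree with the directly computed sample moments (default tolerance
10%; the criterion is insensitive to some non-lognormal inputs, e.g. a
uniform on [1, 2], and that insensitivity is intentional — it mirrors
the published check, which is a sanity check rather than a
goodness-of-fit test; no formal K-S/A-D testing is performed).
`modeMedianToParams()` inverts the mode/median identities exactly, and
is how the bundled tract presets are rebuilt from published values.
`qqLognormal()` pairs sorted log-samples with standard-normal
quantiles at plotting positions `(i - 0.5)/n`; the reference line runs
through the quartiles, so an exact normal quantile grid lies on it
identically. Tortuosity values of exactly zero (perfectly straight
synthetic axons) are excluded from log-based fits.

Tract statistics pool **per-axon averages** (each axon's mean over its
stations), not the raw station values; the per-station table is
retained so the other convention is a one-liner.

## The in silico volume generator

`generateRVE()` builds a periodic box (default 15 x 15 x 15 um) of
non-overlapping elliptical tubes matching a `TractStats` summary. The
published description grants the generator latitude; this
implementation makes every choice explicit and every stochastic step
seeded:

1. Axon count = round(density x box volume).
2. Per-axon mean areas ~ lognormal(areaMu, areaSigma) truncated at the
   0.2 um resolvable outer diameter; ellipticity uniform on the tract
   range; in-plane orientation uniform.
3. **Volume-fraction governs scale.** The published density, area
   distribution and volume fraction are mutually inconsistent:
   density x E[area] implies volume fractions near 0.6–0.65, far above
   the printed 0.37–0.51. The generator keeps the count (density) and
   the distribution *shape*, and uniformly rescales all areas so the
   realised volume fraction hits the printed target — the rescale step
   applied analytically before placement and again, in small verified
   steps, after growth.
4. **Coherent undulation.** Tortuosity is produced by a shared smooth
   lateral displacement field (a few Fourier modes, wavelengths kept
   >= ~5 um so bend radii stay above the axon calibre) plus a small
   independent per-axon jitter (<= 0.05 um). A shared displacement
   translates every z-plane rigidly, so it cannot create overlaps —
   which is what makes the printed tortuosity means attainable at
   packing fractions near the jamming limit; fully independent random
   walks of the required ~0.5 um amplitude cannot respect non-overlap
   at volume fraction 0.5. The field amplitude is calibrated by
   bisection (tolerance 0.005) against the tortuosity *as the
   measurement stage computes it* (per-slice centres, 5-station
   smoothing, 1 - chord/arc). The cost of coherence is a narrower
   per-axon tortuosity spread than the published SD; the achieved
   spread is recorded in `achievedStats()`.
5. **Placement** is random sequential addition, largest first, in the
   periodic x-y cell: candidates are rejected if the un-jittered base
   section would come within `minGap` (default 0.02 um, one in-plane
   voxel; extra-cellular gaps measure tens to hundreds of nanometres)
   of any placed tube at any station plane, periodic images included.
   Ellipse clearance is decided exactly (transform to the frame where
   one ellipse is the unit circle, then Newton-refined minimum
   boundary distance after a 48-point scan). Stubborn configurations
   redraw the candidate's orientation periodically and, if placement
   still stalls, shave all base sections by 1% and retry a fresh
   sequence (the volume-fraction step regains the loss).
6. **Growth** walks the stations in z, applying multiplicative
   lognormal area jitter (CV `interlayerAreaCv`, default 0.10) with
   the slice-to-slice semi-axis change capped at
   `interlayerSemiaxisDelta` (default 0.05 um); a station whose
   jittered section would violate clearance is redrawn (<= 50 times)
   and then shrunk toward the base size, which is clear by
   construction. Interlayer defaults are package conventions — no
   printed values exist for them.
7. A final exact-gap verification over every station and periodic
   image must pass; the generator fails loudly rather than emit an
   overlapping volume.

`validateRVE()` closes the loop: the volume is voxelised (full
periodic grid for volume fraction and density; tight per-axon grids
for morphometry) and re-measured with the same measurement stage used
on real stacks. On generated volumes the measured volume fraction
agrees with the analytic value to ~0.5%, per-axon mean areas to within
5%, and tortuosity means to three decimals.

`exportSTL()` lofts each tube's per-station footprint rings (32
vertices, rings normalised counter-clockwise so walls and caps wind
consistently outward), caps the ends flat at the box faces, and clips
boundary-crossing tubes to the box with the wrapped remainder emitted
as separate closed shells. Every shell must pass the watertightness
check (each edge shared by exactly two triangles, Euler characteristic
2) before anything is written. Units are micrometres. Enclosed-volume
round trips through the written files agree with the generator's
volume fraction to ~1% (the inscribed 32-gon accounts for -0.64%).

## Numerical choices and degenerate inputs

* Intensities live on [0, 1] internally; 16-bit data are rescaled on
  construction and quantised back on write.
* Thresholding uses strict inequality; ties go to black.
* Polygon areas use the shoelace formula; self-intersection and
  collinear degeneracy raise errors rather than silently returning
  nonsense.
* Single-slice axons (no direction), empty plane intersections,
  sub-resolution sections, and volumes with no labels all raise
  descriptive errors; per-axon failures inside `measureVolume()` are
  collected in the `failures` field, never dropped silently.
* All generators are pure functions of (configuration, seed); the RNG
  state of the caller is restored.

## Problem sizes used by the test-suite and reproduction script

Unit and property tests run on reduced instances chosen for the
property under test: 320 px phantoms for the myelin round trips
(independent 764 x 1024 runs confirm size does not matter), 4–6 um
boxes for generator properties, 50,000-draw simulations for the
lognormal recovery checks, and full 15 um boxes wherever a published
tract-level value is the anchor. The acceptance script regenerates
everything it reports at the published scale: 15 x 15 x 15 um volumes
voxelised at 0.020 x 0.020 x 0.150 um and 764 x 1024 phantom images.
Cross-section stations are measured at every 6th station (0.9 um
apart) when only per-axon means are needed; means over ~17 sections
are stable to well under the tolerances involved.

## Known limitations

* All fibres run nominally along z ("unidirectional bundles");
  entangled or crossing-fibre configurations are out of scope.
* The generator's per-axon tortuosity spread is narrower than the
  published SD (see above); the mean is matched.
* Myelin is treated as the outer axon boundary — no inner/outer
  decomposition, no g-ratio.
* Glial somata contribute to the white-pixel count, as in the
  published analysis.
* The phantom contrast conventions (background at 30%, myelin at 75%
  of the dynamic range) are fixed conventions, not calibrated to any
  deposited dataset.
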