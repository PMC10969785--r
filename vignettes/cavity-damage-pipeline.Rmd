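---
title: "Quantifying internal compression damage in citrus from CT sections"
author: "pulpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying internal compression damage in citrus from CT sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulpscan)
```

## The problem

Mandarins compressed during picking, sorting or stacked transport can suffer
internal pulp damage long before the peel shows any rupture. On a grayscale
CT section the fruit reads as a bright peel annulus around mid-intensity
pulp wedges, with a dark cavity at the fruit axis. Compression enlarges that
central cavity, and at larger deformations ruptured pulp falls into it,
appearing as bright *blockage* fragments inside the dark void. The cavity's
pixel area is therefore a usable damage gauge: with $S_1$ and $S_2$ the
cavity areas before and after compression, the damage rate is

$$A = \frac{S_2 - S_1}{S_1} \times 100\%.$$

`pulpscan` implements the section-image segmentation that measures $S_1$ and
$S_2$, the damage-rate and storage-quality statistics built on them, and the
linear models that link compression deformation (mm) to damage rate
($Y_1$, %) and storage decay rate ($Y_2$, %). Because no CT scans are
published with the study this package follows, a phantom generator with
exact pixel ground truth stands in for real scans everywhere a test needs an
image.

## The segmentation pipeline

`extractCavity()` runs seven stages, retained as named intermediates for
audit:

1. **Binarization (A).** Global threshold, Otsu by default; foreground is
   *strictly above* the threshold, so tissue is foreground and
   cavity/background are not. Strict `>` is a deliberate convention: re-runs
   are bit-stable and boundary values are never ambiguous.
2. **Mask construction (B).** The largest foreground component is the fruit
   disk. Its enclosed holes are filled first — the cavity itself is a hole
   in the binarized fruit, and a mask that excluded it would be useless —
   then the component is eroded by a disk-shaped structuring element. The
   erosion-core radius is the knob that adapts the mask to section
   geometry: defaults are 15 px for cross sections and 25 px for
   longitudinal sections at 512 × 512, calibrated on the phantom suite.
   Eroding far enough removes the peel and everything outside it.
3. **Image multiplication (C).** Pixelwise product of image and mask:
   intensities survive inside the mask, the exterior becomes exactly zero.
4. **Cavity isolation (D).** Dark (at-or-below-threshold) pixels inside the
   mask are candidate cavity; the zeroed exterior is background by
   construction and cannot merge with them. Among candidate components the
   cavity is the one whose centroid lies nearest the fruit centroid, with
   ties going to the larger component — compression damage concentrates
   near the fruit axis, so centroid proximity, not size, is the primary
   cue (a big dark defect at the periphery must not win).
5. **Refinement (E, F).** For blocked cavities only: a closing (dilation
   then erosion, default radius 2 px each) severs thin bright bridges
   between blockage fragments and the surrounding tissue so the fragments
   are properly enclosed.
6. **Region-growing fill (G).** Growth from a seed (candidate centroid by
   default) across every pixel enclosed by the cavity boundary — dark
   cavity pixels and bright blockage alike. Formally the growth set is
   the candidate foreground united with its enclosed background
   components; a seed in exterior background is an error.
7. **Measurement.** For an unblocked cavity the candidate component's pixel
   count is the area directly; for a blocked one the filled mask's count
   is used, so blockage area is absorbed into the cavity area, matching
   the definition of the cavity as a region rather than a set of dark
   pixels.

A cavity is *blocked* when enclosed bright pixels strictly exceed 1% of the
cavity area (`blockageFractionThreshold = 0.01`). No criterion is inherited
from prior work here; 1% is far above stray-pixel noise yet far below any
real fragment, and the strict inequality keeps the boundary case
deterministic.

Morphology, component labeling and region growing are implemented in
compiled code with explicit conventions: pixels outside the image are
background, structuring elements are odd-sized logical matrices anchored at
their centre, and connectivity (8 by default, 4 optional) applies to both
foreground growth and background enclosure. The test suite holds these
primitives to brute-force set-definition oracles on hundreds of random
grids at both connectivities, and cross-checks erosion/dilation against
EBImage.

Areas are raw pixel counts throughout: the damage rate is a ratio, so
physical pixel calibration cancels and is deliberately not modelled.

## The phantom generator

`generateSection()` renders, at configurable size (default 512 × 512,
a desk-scale stand-in for the 1920 × 1536 scanner matrix), a fruit of
radius 210 px with an 18 px peel, nine pulp wedges separated by 3 px septa,
and a central cavity shaped as an ellipse (semi-axes 60 × 48 px) with a
five-lobed outline perturbation (amplitude 0.12) so the mask and isolation
stages face an irregular, not analytic, boundary. Optional extras are
bright convex blockage fragments (1–5 per section, wholly inside the
cavity, at least 2 px clear of its wall), point-like dark pulp ruptures,
and additive Gaussian noise clipped to the 0–255 range (default sd 4).
Intensity levels are background 5, cavity 15, rupture 40, septum 120,
pulp 170, blockage 200, peel 230: the cavity is the darkest interior
level, septa sit between the global threshold and pulp so they bind to
tissue, and an inversion flag serves modalities with opposite polarity.
The grayscale polarity of reconstructed CT views is not standardized, so
dark-cavity-on-bright-pulp is a recorded configuration choice, not an
assumption about all scanners.

Ground truth is exact: the label grid is recorded before noise, the cavity
area is the exact count of cavity-region pixels (blockage included), and
identical specs (including the seed) render byte-identical images. A
pre/post pair shares one seed, so both sections depict the same fruit —
same wedge rotation, same lobe phase — and a zero-deformation pair has a
true damage rate of exactly zero.

`tableCalibratedDamageModel()` maps deformation to cavity growth using the
study conditions as calibration anchors: mean damage rates of 3.82, 5.74,
10.81 and 16.58% at 4, 8, 12 and 16 mm, with per-fruit Gaussian scatter
matching the reported group standard deviations (0.35, 0.46, 0.89, 1.07),
linear interpolation between anchors, linear extrapolation beyond, and
truncation at zero. Blockage begins above 10 mm (none is reported at 4 and
8 mm) and ramps to a blockage fraction of 0.15 at 12 mm and 0.25 at 16 mm.
The post-compression cavity semi-axes are scaled by the square root of the
area factor, so the target area is met up to pixel discretization.

**What the phantom does not emulate** — and hence what passing tests do not
show about real data: CT reconstruction artifacts (beam hardening, rings,
streaks), partial-volume blur at tissue boundaries, intensity
inhomogeneity across the field, juice-filled or collapsed cavities whose
contrast with pulp is weak, and blockage that touches the cavity wall over
a long arc. Recovery within 2–3% on phantoms bounds discretization and
pipeline error, not scanner error.

## Statistics

* `damageRate()` evaluates $A$ exactly and preserves negative values —
  cavity shrinkage is information, not an error. `summarizeDamage()`
  reports group means and sample standard deviations (n − 1). The source
  table's "±" is not labelled SD or SEM; it is treated as SD here, a
  recorded assumption.
* `decayRate()` is the percentage of decayed fruits in a group; the decay
  protocol scored a dedicated subgroup of 20 fruits per level (storage
  groups held 45), so group size is an explicit per-metric parameter
  defaulting to 20.
* `respirationRate()` is $(C_1 - C_2)V/(mt)$ in mL kg⁻¹ h⁻¹, with the CO₂
  concentrations treated as volume fractions (their unit is not stated at
  the source; this makes the dimensions close). Negative rates warn but
  return.
* `percentChangeVsControl()` uses the "lower than control is positive"
  sign convention of the storage analyses.
* `fitRateModel()` is ordinary least squares via `lm()`, with
  $R^2 = 1 - SSE/SST$ and a classical two-sided t-test of the slope on
  n − 2 degrees of freedom (NA when n < 3 or the fit is exact). The
  "coefficient of significance" reported alongside the published models is
  interpreted as this p-value — an assumption, since the term is not
  defined there. Control groups (X = 0) are excluded from fits by default
  because the published fits cover the 4–16 mm treatment range; inclusion
  is a flag.

Fitting decay rate on deformation over the four treatment groups gives
slope $210/80 = 2.625$ and intercept $2.5$ in rational arithmetic, an $R^2$
that displays as 0.97, and a slope p-value below 0.05 — the package's tests
assert exactly this. Fitting the *damage-rate group means* gives slope
≈ 1.084 and intercept ≈ −1.60, which does **not** reproduce the published
per-sample damage model ($Y_1 = 0.964X - 0.468$, $R^2$ 0.94): that fit was
evidently made on per-fruit values that were never published. The package
reproduces what the published numbers allow, and `rateModelReport()` flags
the discrepancy when reference coefficients are supplied, rather than
forcing agreement.

## Numerical choices and degenerate inputs

* Otsu on a constant image is undefined: the maximum is returned with a
  warning so strict-`>` binarization yields all background.
* An erosion core that annihilates the fruit component, an empty candidate
  after refinement, a blank image, and a region-growing seed in exterior
  background are all explicit errors; `extractCavity()` re-signals them
  with the failing stage named, and `runPipeline()` isolates them per
  sample (a batch of 120 fruits must survive one bad slice) while
  reporting the failure count — samples are never silently dropped.
* Coordinates are 1-based row/column matrix indices, the native R
  convention; component labels are assigned in raster order, making label
  numbering deterministic.
* `damageRate()` rejects $S_1 \le 0$; a single-record group reports SD 0
  with an explicit `sd_defined = FALSE` flag.
* 8-bit TIFF I/O round-trips integer 0–255 images exactly; 32-bit float
  slices are stored normalized to [0, 1] (the float TIFF writer's reliable
  range), which the loader reports via `valueRange`.

## Problem sizes in the test suite

Unit tests run on 160 px phantoms (cavity ≈ 1 250 px) with a 6 px erosion
core; property tests use up to 16 × 16 random grids (200 for the morphology
oracles, 100 random phantom specs for truth consistency, 100 random OLS
data sets). The acceptance-grade tests use the full 512 px defaults: 30
noiseless phantoms per class for recovery, 8 end-to-end pairs, and 30 pairs
per deformation level for the group-mean emulation, sizes chosen so the
whole suite stays comfortable on a single CPU while keeping discretization
error an order of magnitude below the tolerances being checked.

## Known limitations

* Single 2-D sections only; no volumetric segmentation or 3-D cavity
  measurement.
* One cavity per section is assumed (the centroid rule picks exactly one
  component); fragmented cavities would need the rule revisited.
* The erosion core is fixed per section kind, not tuned per image.
* Peel-damage analysis is out of scope; the peel is only ever masked away.
* The damage model's blockage onset and magnitude are qualitative
  calibrations (blockage is described, not quantified, at the source);
  only the damage-rate means and spreads are quantitatively anchored.
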