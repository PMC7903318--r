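---
title: "Segmenting root systems in soil CT volumes: methods and design"
author: "rootCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting root systems in soil CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootCT)
```

## The problem

X-ray CT of a plant growing in a soil-filled pot yields a 3D attenuation
volume in which roots differ from the surrounding soil matrix by only a
small attenuation offset, while stones, pores and the pot wall differ by a
lot. Roots span two very different shape regimes: fine laterals a few
voxels across, and storage roots (cassava, potato) tens of voxels across.
No single filter handles both, which is why the segmentation here runs two
parallel detection branches and fuses them:

1. a **multiscale Hessian vesselness** branch for fine tubular roots, and
2. a **local 3D-variance homogeneity** branch for thick storage roots,

followed by a median filter, a minimum-volume component filter, curve
skeletonization, a directed root graph, and the trait report.

All tunables live in one `ParameterSet` object `P` — attenuation window
`(aMin, aMax)`, diameter list `dRoot`, fusion thresholds `theta1`/`theta2`,
minimum component volume `vMinMm3`, post-processing options — which is held
constant over a whole time series, so that measurements at different days
are comparable.

## Geometry conventions

Volumes are arrays indexed `[depth, y, x]`: axis 1 is the depth axis, slice
1 is the top of the pot, indices increase downward. Voxels are cubic with
edge `voxelSizeUm`. A voxel with index *i* covers the interval
`[(i-1)v, iv]` mm, its center sits at `(i - 0.5) v`. Depth quantiles are
measured from the *mean soil-surface depth*, not from slice 1, because pots
contain head-space air.

## Preprocessing

**Pot removal.** The wall material attenuates far more than soil, so wall
voxels are selected by an attenuation range and a circle is fitted to the
inner boundary per slice (innermost wall voxel per angular bin, algebraic
least-squares fit). Slices without a detectable ring inherit the nearest
fitted slice. Everything at radius `>= innerRadius - soilMarginMm` is set
to the background sentinel 0; the margin defaults to twice the wall
thickness, since a thin layer of wall-adjacent soil carries strong
partial-volume gradients.

**Attenuation window.** Voxels outside `(aMin, aMax)` are set to 0; inside
values are *kept*, not binarized, because both branches need the gray
structure. Zero was chosen as the sentinel (rather than clamping) so that
the vesselness background is empty; windowing is idempotent.

**Soil surface.** Per horizontal position, the first depth whose value
exceeds an air/soil cut (default: midpoint of `aMin` and the soil mode).
The entry point is the centroid of the topmost connected cluster of
voxels deviating from the soil mode toward the root polarity by more than
two robust standard deviations; tiny clusters (isolated texture dips) are
ignored because the stem plug crossing the surface has root-scale
cross-section.

## The vesselness branch

At each target diameter `D` in `dRoot` the volume is smoothed with a
Gaussian of `sigma = D/2` (radius matching, the standard convention —
validated by the scale-selection property below), second derivatives are
taken by central differences and gamma-normalized by `sigma^2`, and the
per-voxel symmetric 3x3 Hessian is diagonalized (cyclic Jacobi, machine
precision). With `|l1| <= |l2| <= |l3|`, a tube has `l1 ~ 0` and a large
equal-signed pair; the vesselness is

$$ v = \left(1 - e^{-R_A^2/2\alpha^2}\right) e^{-R_B^2/2\beta^2}
       \left(1 - e^{-S^2/2c^2}\right),\qquad
   R_A = |l_2|/|l_3|,\; R_B = |l_1|/\sqrt{|l_2 l_3|},\;
   S = \sqrt{l_1^2+l_2^2+l_3^2}, $$

zero where the eigenvalue signs violate the tube condition for the chosen
polarity. Roots in mineral soil attenuate *less* than soil (water vs
mineral), so the default polarity is `"dark"` (`l2, l3 > 0`); the bright
condition is the mirror image. The response is the voxelwise maximum over
scales, multiplied by `responseScale` (default 65535) so thresholds are
stated on a 16-bit gray-value scale.

Two numerical choices matter:

* `alpha = beta = 0.5` (the classical defaults; exposed in the API).
* The structure-norm constant `c` is **shared across scales**. A per-scale
  adaptive `c` (half the per-scale maximal `S`) normalizes every scale's
  response to the same ceiling and destroys scale selectivity; with a
  shared `c` the gamma-normalized magnitude peaks at `sigma = D/2`, which
  is exactly the property the test-suite asserts on analytic Gaussian
  tubes. By default `c` adapts to the volume (half the maximal `S` over
  all scales); for *batch* runs the `ParameterSet` can pin `frangiC` to a
  constant, because an adaptive `c` couples the response scale — and
  therefore the meaning of `theta1` — to the brightest incidental
  structure in each particular volume (usually a stone rim), which breaks
  the one-parameter-set contract across a time series. The shipped phantom
  presets pin it.

## The variance branch

Thick storage roots are nearly homogeneous inside, while soil is textured;
at a Gaussian scale `lambda` the local variance

$$ V_{local} = G_\lambda * I^2 - (G_\lambda * I)^2 $$

(clipped at zero for floating-point residue) is therefore low inside
storage roots. `theta2` is an **upper** bound: a voxel is a storage
candidate if it is inside the attenuation window and `V_local <= theta2`.
Two supports make this usable:

* **Thickness test.** Candidate components must be thicker than
  `max(dRoot)` (twice the maximal inscribed-ball radius from the exact
  Euclidean distance transform). Without it a permissive `theta2` admits
  arbitrary homogeneous soil; with it, only structures wider than anything
  the vesselness branch is responsible for can enter. This reading is
  consistent with the shipped cassava preset, whose `theta2 = 65000` is
  essentially the 16-bit ceiling — "maximally permissive" — so the
  discrimination must come from the window plus a structural test, not
  from the variance bound itself.
* **Masked statistics and rim recovery.** The pipeline evaluates the
  variance with weights renormalized over in-window voxels
  (`maskedZeros = TRUE`), so window-clipped soil next to a storage root
  does not contribute artificial contrast; voxels whose neighbourhood
  holds less than 30% in-window weight get a prohibitive response. The
  partial-volume rim of a storage root still carries genuine gradient
  variance, so after the thickness test the surviving components are
  grown back by `varianceDilateVox` voxels (default 1.5 lambda),
  restricted to the window. Both knobs can be disabled, which recovers
  the plain textbook definition that the unit tests check against an
  explicit windowed-convolution oracle.

## Fusion and cleaning

`mask = (vesselness >= theta1) OR (storage-candidate support)`. Raising
`theta1` or lowering `theta2` never adds voxels (monotonicity is asserted
as a property test). An optional binary median filter (majority vote in a
`k^3` box, zero-padded) regularizes the mask; note that a 3x3x3 kernel can
sever tubes near the resolution limit, which is why the phantom presets
leave it off while the bean presets (whose lateral roots are oversampled)
use it. Components smaller than `vMinMm3` are removed; component volume is
voxel count times the cubic voxel volume, and connectivity defaults to 26.

## Skeleton and root graph

The mask is thinned by six directional subiterations that delete only
*simple* voxels (removal preserves topology; characterized by exactly one
26-connected foreground component among the 26 neighbours and exactly one
6-connected background component in the 18-neighbourhood touching a face
neighbour), never curve endpoints. The result is a 1-voxel-wide centred
curve skeleton; thinning is idempotent and preserves component count.

Graph nodes sit at skeleton voxels with other than two neighbours, plus
the entry (the skeleton voxel nearest the detected entry point; ties break
by depth, then lexicographically). Edges are the voxel chains between
nodes, directed away from the entry by breadth-first search; rare cycles
from thinning are broken by dropping the longest edge in each cycle (the
minimum-spanning-tree rule). Thinning blunt tube ends leaves short spurs,
so terminal edges shorter than `pruneVox` attached to a junction are
pruned (the pipeline default is `max(dRoot)` voxels — a spur shorter than
the thickest root's radius cannot be a real lateral), as is an upward
terminal stub at the entry node (the stem above the soil is not root).
Only the entry component is graphed; other components are counted and
reported (`extraComponents`) and still contribute to volume-based traits.

Root length is reported in two conventions: the primary one counts
distinct skeleton voxels times the voxel edge (simple and matching the
trait definitions downstream), the Euclidean variant sums polyline segment
lengths. The voxel-count convention systematically undercounts diagonal
runs (up to `sqrt(3)` per step); the Euclidean variant slightly overcounts
smooth curves because a voxel chain zigzags. Validation against phantom
ground truth uses the Euclidean variant for that reason.

## Traits

* `V_root`: voxel count x voxel volume.
* Depth profile: per-slice volume below the per-column soil surface;
  quantile depths interpolate linearly *within* a slice, measured from the
  mean surface depth. A density-weighted profile variant is available
  (`weightVol`), the volume-based one is primary.
* Form fraction `F = 100 V_root / V_hull`: the hull is built over the
  *corners* of candidate voxels (per-slice 2D hull reduction, then an
  incremental 3D hull), so a solid cube scores exactly 100% and `F <= 100`
  by construction. Coplanar masks raise an error for `F` (no 3D hull), but
  not for the angle report, where a flat plate legitimately reports 0°.
* Root angles: hull faces whose outward normal points toward the surface
  (negative depth component) are "top faces"; each contributes the
  dihedral angle between its plane and the horizontal, `theta_mean` is
  area-weighted (the natural face-based aggregate; minimum and maximum are
  taken over the same faces).
* Densities: per-voxel density is gray value x attenuation; root mean over
  mask voxels, soil mean over pot-interior non-root voxels, their ratio in
  percent, and the mean over the non-root halo within `radiusMm` (default
  1 mm) of the mask.
* Tips: graph nodes without outgoing edges.

The RSML export nests roots by graph topology (edges leaving the entry are
top-level roots, edges leaving an edge's head are its laterals), writes
polylines in mm at full double precision (so a parse round-trip is exact),
and performs structural validation (metadata with version and unit, scene,
plant, polylines with at least two numeric points).

## The phantom generator

Real scans of the kind this pipeline targets are not redistributable, so
the package ships a generator that produces synthetic pots with complete
ground truth: a recursive root tree (segments that branch with a given
probability into two laterals on opposed azimuths, taper linearly with
tree level, wander with a small angular jitter and a gravitropic bias, and
stay inside the pot), rasterized as tubes with a half-voxel edge profile,
in soil modeled as a correlated Gaussian random field, with stones and
pores as random ellipsoids outside the attenuation window, a dense pot
annulus, a global Gaussian blur for partial-volume effects and additive
voxel noise. Truth (mask, centerlines, volume, length, tip count, entry,
surface) is recorded before degradation.

Default conditions, chosen once: roots at attenuation 0.15 against soil
mean 0.18 with the bean window (0.11, 0.24); soil matrix sd 0.004 at 4
voxel correlation plus voxel noise sd 0.006 and blur sigma 0.6. The split
between a weak smooth matrix field and stronger uncorrelated noise encodes
that within-window soil heterogeneity is fine-grained (sub-voxel
granularity averages into noise), while coarse heterogeneity (stones,
pores) sits outside the window and is modeled separately. An early variant
with a strong matrix field at 2-3 voxel correlation produced percolating
dark filaments at exactly the root scale — a level-set artifact of
Gaussian random fields rather than a property of real soil, and one that
no parameterization of this (or any threshold-based) method separates.
Storage-root phantoms use soil mean 0.26, mostly above the window top,
emulating the sieved-potting-mix regime in which the homogeneity branch
with a permissive `theta2` is the designed detector.

Two generator properties are *correctness requirements*, not realism
knobs: independent branches keep a surface-to-surface clearance larger
than the segmentation's boundary uncertainty (4.5 voxels), and
collision-stopped stubs shorter than three quarters of a segment are
discarded (the parent reverts to a tip). Without them the ground-truth
leaf count is not the topological tip count of the rasterized mask, and no
segmentation could be scored against it.

What the phantoms do **not** model: beam hardening, scatter, ring and
ghosting artifacts, soil moisture drift, root-attenuation gradients, or
roots touching each other (real laterals do). Passing the phantom suite
therefore demonstrates the pipeline's internal consistency and its
behaviour under controlled low contrast and noise — not performance on
any particular scanner's data.

## Parameter presets

`presetParameters()` ships the published parameter sets for bean small pot,
bean medium pot and cassava (attenuation windows (0.11, 0.24)/(0.08, 0.2),
diameter lists, `theta1` 400/600/60, `theta2` 2500/2000/65000, `V_min`
1/1.6/5 mm^3), and two presets calibrated for the shipped phantom
generator (`phantom`, `phantom_storage`). The phantom presets were
calibrated once on designated calibration phantoms (seeds 1-3 for the
fine-root preset, seed 5 for the storage preset) — the in-silico analog of
the published procedure, where `P` is adapted manually once on the first
scans of an experiment — and then held fixed for every validation seed.
Their `theta1 = 8000` is on the same 16-bit response scale with
`frangiC = 0.006` pinned; `theta2` is `1e-6` for the fine preset (the
variance branch has no work on fine-root phantoms and in-window soil must
not leak through it) and `1e-3` — permissive, cassava-style — for the
storage preset; `V_min = 20` mm^3 removes rim artifacts of stones and
pores, which is safe because a connected root system is two orders of
magnitude larger.

## Problem sizes used in the validation suite

The test and acceptance phantoms use 34 mm pots at 400 um voxels (volumes
around 90 x 103 x 103) for fine-root recovery, 56 mm pots at 500 um voxels
for the storage capsule, and 70 mm pots at 700 um for growth series —
sizes at which a full pipeline run takes seconds while every structural
regime (fine laterals near the detectability limit, a >40-voxel storage
root, multi-step growth) is represented.

## Known limitations

* Threshold detection shaves the weakly-responding last voxels of tapering
  root tips; recovered convex hulls are slightly smaller than truth hulls,
  so the form fraction is biased a few percent high even when total volume
  and length are recovered to within a few percent.
* The local-variance branch cannot separate storage roots from soil whose
  in-window texture variance matches the root interior; it relies on the
  attenuation window doing part of the work, as in the sieved-soil regime.
* The voxel-count length convention is biased low on oblique roots; use
  the Euclidean output when comparing against physical lengths.
* Pot detection assumes an approximately circular wall per slice;
  rhizotrons and square pots are out of scope.
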