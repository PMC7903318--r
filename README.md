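# rootCT

Semiautomatic segmentation of plant root systems in X-ray CT volumes of
soil-grown plants, with a full architectural trait report and RSML export.

Roots in soil CT scans are low-contrast: a root differs from the
surrounding soil matrix by only a small attenuation offset, and root
systems mix fine laterals a few voxels across with storage roots tens of
voxels across. `rootCT` segments both regimes with two parallel detection
branches fused under one parameter set *P*:

* **Fine roots** — multiscale Hessian vesselness. At every target
  diameter `D` in `dRoot`, the gamma-normalized scale-space Hessian
  (`sigma = D/2`) is diagonalized per voxel; with
  `|λ1| ≤ |λ2| ≤ |λ3|`, tubes satisfy `λ1 ≈ 0` with a large equal-signed
  pair, and the response

  `v = (1 − exp(−R_A²/2α²)) · exp(−R_B²/2β²) · (1 − exp(−S²/2c²))`,

  `R_A = |λ2|/|λ3|`, `R_B = |λ1|/√|λ2λ3|`, `S = √(λ1²+λ2²+λ3²)`,

  is maximized over scales and thresholded at `theta1`.
* **Storage roots** — local 3D variance
  `V = G_λ∗I² − (G_λ∗I)²` is low inside homogeneous thick roots;
  voxels inside the attenuation window with `V ≤ theta2` that belong to
  components thicker than `max(dRoot)` (distance-transform test) pass.

The fused mask is cleaned (optional binary median filter, minimum-volume
component filter `V_min`), thinned to a topology-preserving curve
skeleton, and converted to a root graph directed away from the stem entry
point. From mask + graph the package computes total root volume `V_root`,
root length `L_root` (voxel-count and Euclidean conventions), biomass
depth quantiles, convex-hull form fraction `F`, hull-face root angles
`θ_min/θ_mean/θ_max`, gray-value densities of root and soil, and the tip
count, and writes the architecture as RSML.

A synthetic phantom generator (`phantomSpec()`, `generateRootTree()`,
`rasterizePhantom()`, `phantomTimeSeries()`) produces root systems in
textured soil inside a pot with complete ground truth, so the entire
pipeline is testable without CT scans.

## Worked example

```r
library(rootCT)

spec <- phantomSpec(seed = 11)                      # 34 mm pot, 400 um voxels
ph   <- rasterizePhantom(generateRootTree(spec), spec)

cfg <- runConfig(params = "phantom", outDir = "out",
                 potWallRange = c(0.3, 0.7), logLevel = "quiet")
res <- runSingle(cfg, volume = ph$volume)
res$traits
```

```
TraitReport
  V_root  : 157.95 mm^3
  L_root  : 78.80 mm (euclid 102.22 mm)
  quantile depths (mm): 25%=11.3 50%=16.9 75%=21.9 90%=24.7
  F       : 9.21 %
  angles  : min 0.0 / mean 74.6 / max 88.3 deg
  density : root 0.0 +/- 0.0, soil 0.0 +/- 0.0, relation 113.8 %
  tips    : 6
```

`V_root` is the segmented volume (ground truth for this phantom is
163.5 mm^3, a 3.4% error), `L_root` the skeleton length on the
voxel-count convention with the Euclidean variant alongside, the quantile
depths locate the biomass below the detected soil surface, `F` relates
root volume to its convex hull, the hull-face angles summarize the root
envelope relative to the soil plane, the density relation is soil/root
density in percent (this phantom's roots attenuate less than its soil;
the phantom is already in attenuation units, hence the tiny absolute
densities), and the tip count equals the phantom's true 6 tips.
Artifacts (mask volume, traits CSV, RSML, parameter log) land in `out/`.

The published parameter sets ship as presets
(`presetParameters("bean_small_pot")`, `"bean_medium_pot"`, `"cassava"`),
and a thin command-line front end for batch runs lives at
`inst/scripts/rootct.R`:

```sh
Rscript inst/scripts/rootct.R run --input scans/ --out results/ --preset cassava
Rscript inst/scripts/rootct.R phantom --out phantoms/ --seed 7 --storage
```

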