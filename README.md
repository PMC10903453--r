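# cristamorph

Quantitative tools for studying how the geometry of mitochondrial ATP
synthase dimers shapes crista membranes.

Mitochondrial ATP synthases assemble into dimers, and dimers into rows
along the sharply curved ridges of crista membranes. The angle between
the two monomer central-stalk axes of a dimer varies between species —
about 86° in yeast and other fungi/mammals, 105° in the nematode
*C. elegans*, up to 120° in potato — and a wider dimer angle folds the
membrane more sharply, producing flatter, more lamellar cristae with a
higher surface-area:volume (SA:V) ratio. `cristamorph` turns that
comparison into a reusable, fully testable pipeline: synthetic crista
membranes decorated with dimer rows are generated with known ground
truth, measured with the same metrics used on cryo-electron tomography
data, and compared statistically between species presets.

For structural and cell biologists, the package provides:

* **Synthetic scenes** — watertight triangulated crista meshes
  (lamellar sacs with a wedge-angled, fillet-rounded ridge), rows of
  dimer poses with Gaussian angular/positional jitter, and voxelised
  label volumes emulating tomographic segmentations
  (`make_crista_mesh()`, `place_dimer_row()`, `make_population()`,
  `voxelize()`).
* **Dimer geometry** — per-dimer angle between monomer axes
  `θ = arccos(a·b)`, central-stalk separation `|b_a − b_b|`, membrane
  curvature (wedge) angle from least-squares flank planes, inter-dimer
  spacing and in-plane yaw offset along rows (`dimer_angle()`,
  `stalk_separation()`, `membrane_wedge_angle()`, `row_metrics()`,
  `measure_dimers()`).
* **Crista morphometrics** — triangle-sum surface area,
  divergence-theorem enclosed volume, per-crista SA:V, and local width
  by inward-normal ray casting, from meshes or MRC label volumes
  (`surface_area()`, `enclosed_volume()`, `crista_width()`,
  `morphometrics()`, `volume_morphometrics()`).
* **Statistics** — Welch's *t*-test on per-crista SA:V (with fold
  change of group means) and the Mann–Whitney *U*-test on pooled
  widths, with conventional significance stars (`welch_t()`,
  `mann_whitney_u()`, `compare_populations()`).
* **Orchestration** — one call (`run_reproduction()`) generates both
  species' scenes, measures them, compares them, and reports every
  measured value next to its ground truth; a thin CLI
  (`inst/cli/cristamorph`) exposes the verbs `simulate`,
  `measure-dimers`, `morphometry`, `compare` and `reproduce`.

Everything is tidyverse-native: measurement functions take and return
tibbles, results have `tidy()`/`glance()` methods and `autoplot()`
figures, and all randomness is controlled by explicit seeds.

## Worked example

Generate a *C. elegans*-preset crista, decorate its ridge with a
jittered dimer row, and measure it:

```r
library(cristamorph)

mesh <- make_crista_mesh("celegans", face_extent_nm = 100, mesh_step_nm = 1)
row  <- place_dimer_row(mesh, "celegans", n_dimers = 7, jitter_deg = 5, seed = 1)
measure_dimers(row, mesh)
#> <dimer_measurements>
#>   7 dimers in 1 rows
#>   dimer angle   103.50 +- 10.34 deg
#>   stalk sep      16.50 +- 0.00 nm
#>   inter-dimer    12.50 nm   yaw 20.00 deg
#>   wedge angle    50.00 deg
```

With 5° of angular jitter on each monomer axis, seven dimers average
103.5° around the 105° ground truth; the noiseless quantities (stalk
separation 16.5 nm, inter-dimer spacing 12.5 nm, yaw 20°, wedge angle
50°) are recovered exactly.

Compare species-matched populations, as in a two-organism tomography
study (47 worm vs 63 yeast cristae):

```r
worm  <- morphometrics(make_population("celegans", 47, seed = 1),
                       n_width_samples = 3, seed = 2)
yeast <- morphometrics(make_population("scerevisiae", 63, seed = 3),
                       n_width_samples = 3, seed = 4)
compare_populations(worm, yeast, group_names = c("celegans", "scerevisiae"))
#> <comparison_report: sa_to_v_per_nm>
#>   celegans       n =  47  mean = 0.1089  sd = 0.008868
#>   scerevisiae    n =  63  mean = 0.07623  sd = 0.003699
#>   fold change (celegans/scerevisiae) = 1.429
#>   Welch t: p = 1.32e-31  [****]
#> <comparison_report: width_nm>
#>   celegans       n = 141  mean = 20.37  sd = 1.849
#>   scerevisiae    n = 189  mean = 30.18  sd = 1.527
#>   fold change (celegans/scerevisiae) = 0.675
#>   Mann-Whitney U: p = 1.82e-54  [****]
```

The narrower worm cristae (20 nm vs 30 nm calibrated widths) carry a
~1.4–1.5-fold higher SA:V ratio at four-star significance — the
hallmark of flatter, more lamellar cristae. `autoplot()` on the
comparison draws the jittered per-crista values with group mean ± SD
and stars.

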