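# cardiotract

Quantitative diffusion tensor (DT) tractography of the left ventricle (LV),
in R.

Myofiber architecture in the heart is described by the **helix angle (HA)**:
the inclination of a fiber out of the LV short-axis plane, measured against
the local circumferential direction. Subendocardial fibers form
right-handed helices (positive HA), midmyocardial fibers run
circumferentially (HA ≈ 0), and subepicardial fibers form left-handed
helices (negative HA). After myocardial infarction, the *remote zone* —
structurally intact myocardium far from the scar — remodels, and its HA
distribution shifts rightward (toward positive angles), most strongly in
the subepicardium. This package implements a whole-tract statistical
framework to quantify that architecture in 3D:

- **Tensor fitting and eigendecomposition** — log-linear least-squares fit
  of the diffusion tensor from diffusion-weighted volumes, per-voxel sorted
  eigensystems (λ₁ ≥ λ₂ ≥ λ₃).
- **Streamline tractography** — bidirectional fourth-order Runge–Kutta
  integration of the primary eigenvector field ê₁ (compiled core), with a
  quarter-voxel step, antipodal sign alignment, a 35° propagation-angle
  termination criterion, and two fiber-length policies: capping total
  length at half the LV circumference (**πR**) or clipping to an ROI.
- **Whole-tract HA classification** — each tract is reduced to the
  minimum, median, maximum and mean of its discrete per-vertex HA.
- **Regional quantification** — two-step (base–apex, then
  anterior–posterior) averaging of the per-tract statistics inside an ROI
  yields three transmural HA curves HAmin(x), HAmed(x), HAmax(x) over
  normalized wall depth x (0 = endocardium, 1 = epicardium), from which:

  - the **tractographic coherence index**

    TCI = ∫ HAmed(x)² dx / [ ∫ (HAmax − HAmed)² dx + ∫ (HAmin − HAmed)² dx ]

    (trapezoidal integrals on normalized depth; > 0.1 for coherent
    πR-length datasets),
  - the median-HA **histogram** and its **variance ratio**
    var(HA < 0)/var(HA > 0) (≈ 1 for normal symmetric architecture, ≪ 1
    after a rightward shift), and
  - the **zero-crossing depth** of the median curve (≈ 0.5 normally,
    displaced toward the epicardium in the remote zone).
- **Histology orientation analysis** — Hessian ridge detection on 2D
  microscopy sections (Gaussian-scale Hessian, single-pixel thinning,
  8-connected segments, length-weighted axial circular mean) for
  independent validation of the transmural HA gradient.
- **Synthetic LV phantom** — an annular wall segment with a prescribed
  transmural HA profile (presets: `normal-human` ±60°, `normal-sheep`
  ±50°, `remote-zone` +60/−37.5°), per-voxel orientation noise, forward
  DWI simulation, and stripe-image fixtures, so that every stage is
  testable against known ground truth.

File formats: NIfTI-1 (`.nii`/`.nii.gz`) volumes and tensor volumes
(6 components per voxel, lower-triangular order Dxx, Dxy, Dyy, Dxz, Dyz,
Dzz, tagged by a header extension), FSL-style `bvals`/`bvecs` text files,
VTK legacy ASCII polydata for tracts (point scalar `HA_deg`, cell scalars
`HA_min/HA_med/HA_max/HA_mean/termination`), ASCII PGM for section images,
CSV/JSON for curves and metrics.

## Worked example

```r
library(cardiotract)

spec <- phantom_preset("normal-sheep", seed = 1)   # +50/-50 deg, 5 deg noise
res  <- run_phantom_pipeline(spec)                 # pi-R length policy

res$tracts
#> tract_set: 2208 streamlines, step 0.25 mm, length 2.0-85.0 mm (median 85.0)
res$tci
#> TCI = 6.65 (numerator 484.3, denominator 72.79, 7 samples)
res$histogram
#> ha_histogram (median HA): 2208 tracts (1157 neg / 1051 pos), variance ratio 0.943
res$zero_crossing$depth
#> [1] 0.5106023
```

The 2,208 tracts seeded in a lateral-wall sector of the 64×64×48 phantom
are capped at πR ≈ 85 mm (R ≈ 27 mm is the effective mid-wall radius).
Their median-HA histogram is symmetric about zero — variance ratio 0.943,
close to the ideal 1.0 of a symmetric ±50° architecture — and the TCI of
6.65 is far above the 0.1 coherence floor, as expected for a clean
phantom. The median curve crosses zero at mid-wall (depth 0.51). Running
the same pipeline on `phantom_preset("remote-zone")` drops the variance
ratio to ≈ 0.33 and moves the zero-crossing to ≈ 0.63 while the TCI stays
in the normal range: the remodeling signature is a coherent rightward HA
shift, not a loss of tract coherence.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/cardiotract.R pipeline --preset normal-sheep --seed 1 --out-dir out/
# writes out/metrics.json (with provenance), curves.csv, histogram.csv, tracts.vtk
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch, the two phantom-reachable headline quantities:
the mean negative/positive variance ratio of the median-HA histogram for
πR-capped tracts on the symmetric normal-sheep phantom over five
independent seeds (`t1`), and the minimum TCI of the corresponding
transmural HA curves across those seeds (`t3`), writing them as JSON to
`--out`.
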