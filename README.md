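# musclePET

Volumetric quantification of [18F]-fluorodeoxyglucose (FDG) uptake in
paired lower-limb muscles from 3D PET volumes and aligned label masks.

After an exercise task performed under FDG, each muscle's glucose
consumption is frozen into the PET image. Given the activity volume
(NIfTI, Bq/mL), an integer label mask of muscle ROIs on the same grid,
and the acquisition metadata (injected dose, uptake time, body mass),
`musclePET` answers three questions per muscle:

* **Is uptake symmetric between limbs?** Per-muscle standardized uptake
  value `SUV = (A/V) / (D*/M)` — total ROI activity `A` (Bq) per volume
  `V` (mL), over injected dose decayed to scan start `D*` (Bq) per body
  mass `M` (g) — and the absolute uptake value `AUV = SUV x V` (g), then
  the symmetry index between dominant (`d`) and non-dominant (`n`) limb
  values, `SI = 100% x (d - n) / ((d + n)/2)` with `ASI = |SI|`, and an
  exact Wilcoxon matched-pair signed-rank test across subjects.
* **Is uptake heterogeneous within a muscle?** The moment skewness
  `g1 = m3 / m2^(3/2)` of the voxel SUV distribution, plus histograms.
* **Do hot voxels cluster?** The top 5 % of ROI voxels are "hot"; NHN
  counts each voxel's hot face-neighbors (6-connectivity, neighbors
  outside the ROI excluded), and the cluster index is
  `mean(NHN_hot) / (mean(NHN_cold) x 19)` with `19 = 0.95/0.05`. Random
  spread gives roughly `(m-1)/(19m) ~ 0.053`; compact aggregation drives
  it above 1. A seeded permutation null calibrates it empirically.

Because no public dataset exists for this kind of study, the package
ships a first-class synthetic phantom generator (`writeFixtureStudy()`,
`makePairedStudy()`): ellipsoidal muscle ROIs on a 1.6 x 1.6 x 2.0 mm
grid, gamma-distributed uptake with controlled skewness, injected
compact hot clusters, exact inter-limb target asymmetry, and 3 mm FWHM
Gaussian post-smoothing — with all ground truth recorded, so every
estimator is validated by recovery tests.

## Worked example

```r
library(musclePET)

cfg <- writeFixtureStudy("readme_study", nSubjects = 10, seed = 42)
res <- runStudy(cfg, outputDir = "readme_out")
res$asiSummary[, c("muscle", "median_asi", "min_asi", "max_asi",
                   "n_subjects_gt_threshold")]
```

```
                 muscle median_asi min_asi max_asi n_subjects_gt_threshold
 gastrocnemius_medialis      48.67    3.41   114.7                       6
         gluteus_medius      12.72    4.35    50.1                       3
       vastus_lateralis       6.29    3.74    24.0                       0
```

The synthetic lower-leg muscle is built with large, variable inter-limb
asymmetry (median ASI ~49 %, six of ten subjects beyond 25 %), the thigh
muscle with near-symmetry — the segment pattern the generator encodes.
Group-level direction is tested per muscle:

```r
res$uptakeSummary[, c("muscle", "suv_dom_median", "suv_nondom_median",
                      "p_suv", "p_auv")]
```

```
                 muscle suv_dom_median suv_nondom_median p_suv p_auv
 gastrocnemius_medialis          1.612             1.925 0.375 0.375
         gluteus_medius          0.864             0.787 0.432 0.432
       vastus_lateralis          0.654             0.680 0.492 0.492
```

Large individual asymmetries, no systematic dominant/non-dominant
direction (all p > 0.05) — asymmetry magnitude without directionality.
One muscle in depth, with the permutation calibration of its cluster
index:

```r
vol  <- readVolume("readme_study/S01/volume_dominant.nii.gz")
mask <- readLabelMask("readme_study/S01/mask_dominant.nii.gz")
ca   <- clusterAnalysis(vol, mask, label = 3, nPermutations = 200, seed = 1)
```

```
cluster index 2.03 (m = 153 hot voxels), permutation p = 0.0050, null mean 0.052
```

The observed index (2.03) sits far above the uniform-shuffle null
(~0.052): the injected hot blobs are detected as genuine spatial
aggregation at the minimum attainable p for 200 permutations.

A thin CLI wrapper with `analyze`, `make-fixtures`, `cluster-index` and
`symmetry` subcommands is installed under `inst/scripts/muscle-pet`.

## Documentation

The methods vignette (`vignettes/muscle-uptake-analysis.Rmd`) describes
the quantification model, the phantom's statistical structure and what
it does and does not emulate, and every numerical convention (rounding,
tie-breaks, degenerate inputs).
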