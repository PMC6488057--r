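---
title: "Volumetric analysis of paired-limb muscle FDG uptake"
author: "musclePET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric analysis of paired-limb muscle FDG uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclePET)
```

## The problem

After a subject performs a prolonged activity (for example treadmill
walking) under [18F]-fluorodeoxyglucose, a PET scan of the lower limbs
records, voxel by voxel, how much glucose each muscle consumed. Given the
activity volume and a 3D label mask assigning each voxel to a muscle ROI,
three scientific questions drive this package:

1. **Symmetry** — is a muscle's uptake the same in the dominant and the
   non-dominant limb?
2. **Heterogeneity** — is uptake distributed evenly across the voxels of
   one muscle, or do most voxels take up little while a minority takes up
   a lot?
3. **Clustering** — when high-uptake ("hot") voxels exist, are they
   scattered through the muscle or spatially aggregated?

The package implements the full quantification chain for these questions,
plus a synthetic phantom generator with recorded ground truth, so every
stage is testable without clinical data.

## Quantification model

**Units and geometry.** Volumes are held as `VolumeGrid` objects: a 3D
array indexed `[x, y, z]` (x fastest, z the slice axis), voxel spacing in
mm (the pipeline's reference geometry is 1.6 x 1.6 x 2.0 mm), and a unit
tag, either activity concentration (Bq/mL) or SUV (g/mL). Masks are
integer `LabelMask` arrays on the identical grid; a voxel belongs to a
muscle if and only if its label equals that muscle's id — masks are
voxelized upstream and no partial-volume weighting is applied. Stored
values are converted to Bq/mL at load time (`applyRescale()` for
slope/intercept-encoded sources), and all downstream math is unit-tagged.

**SUV.** For muscle $i$ with total measured activity $A_i$ (Bq) and
volume $V_i$ (mL), injected activity $D$ (Bq) and body mass $M$ (g):

$$\mathrm{SUV}_i = \frac{A_i / V_i}{D^* / M}, \qquad
  D^* = D \cdot 2^{-\Delta t / T_{1/2}}$$

where $\Delta t$ is the injection-to-scan interval and $T_{1/2}$ the
isotope half-life (109.77 min for fluorine-18). The decay correction is
applied to the denominator — i.e. the injected dose is decayed to scan
start; decaying the uptake back to injection time instead is
algebraically identical. $A_i$ is computed as the mean ROI concentration
times $V_i$, which makes $\mathrm{SUV}_i$ exactly the voxel-mean of the
voxelwise SUV map; with uniform spacing this equals summing per-voxel
activities. The absolute uptake value $\mathrm{AUV}_i = \mathrm{SUV}_i
\cdot V_i$ (g) undoes the volume normalization so that inter-limb volume
differences carry through.

**Symmetry.** For dominant/non-dominant values $d, n$:

$$\mathrm{SI} = 100\,\% \times \frac{d - n}{(d + n)/2}, \qquad
  \mathrm{ASI} = |\mathrm{SI}|$$

SI is antisymmetric under limb swap, invariant under common rescaling,
and bounded by $\pm 200\,\%$ (one limb silent). Group comparisons use a
Wilcoxon matched-pair signed-rank test: exact for $n \le 20$ by
enumerating all $2^n$ sign assignments (midranks for ties; two-sided
$p = \min(1, 2\min(P(W \le w), P(W \ge w)))$), tie-corrected normal
approximation above. Zero differences are dropped (reducing $n$), the
common convention. No multiple-testing correction is applied across
muscles by default — the analysis convention this package reproduces
reports uncorrected $P \le 0.05$ — and a Kolmogorov-Smirnov screen
against a normal with estimated mean/sd motivates the non-parametric
choice. Estimating those parameters from the sample makes the plain KS
screen anticonservative (the Lilliefors situation); it is retained
deliberately as a screening device only.

**Heterogeneity.** Within-muscle shape is summarized by the moment
skewness $g_1 = m_3 / m_2^{3/2}$, without small-sample bias correction:
muscle ROIs contain thousands of voxels, where $g_1$ and the adjusted
$G_1$ differ negligibly, and $g_1$ is the simpler contract. Skewness is
invariant under positive affine maps, so it is identical on Bq/mL and
SUV values.

**Clustering.** Within one ROI of $N$ voxels, the
$m = \max(1, \mathrm{round}(0.05\,N))$ highest-valued voxels are "hot"
(half-up rounding keeps $m/N$ closest to the 5 % target and guarantees a
nonempty hot set; ties at the cutoff are broken by lexicographic voxel
index for reproducibility, and flagged). For every ROI voxel, NHN counts
its face-adjacent (6-connectivity) neighbors that are hot; neighbors
outside the ROI are excluded entirely — voxels of other tissues have no
hot/cold status. The cluster index is

$$\mathrm{CI} = \frac{\tfrac1m \sum_{h} \mathrm{NHN}_h}
  {\tfrac1n \sum_{c} \mathrm{NHN}_c \times 19}$$

with $19 = (1 - f)/f$ at $f = 0.05$ generalizing to other hot fractions.
Note the unusual normalization: under uniformly random hot placement the
expected index is $\approx (m-1)/(19\,m) \approx 0.053$, not 1, so
"close to zero" means homogeneous spread while values above one indicate
strong aggregation. The formula is implemented verbatim;
`permutationNull()` provides the empirical calibration (uniform
reshuffles of the hot flags, $p = (1 + \#\{\mathrm{null} \ge
\mathrm{obs}\})/(B + 1)$) so users can judge an observed index against
its own ROI geometry rather than against a nominal scale. 6-connectivity
treats all face neighbors equally despite anisotropic voxels, matching
the algorithm the index originates from; no distance weighting is
applied.

## The synthetic phantom

No public dataset accompanies this analysis domain, so the generator is
a first-class module. One subject's study is parameterized by a
`PhantomSpec`:

* **Geometry** — per-muscle axis-aligned ellipsoids on a 64 x 64 x 96
  grid at 1.6 x 1.6 x 2.0 mm (kept small enough that the full test suite
  runs in minutes; the analysis itself is resolution-agnostic). The
  non-dominant limb is the mirrored geometry (an exact array flip, so
  voxel counts match).
* **Background** — i.i.d. gamma draws per muscle. Gamma was chosen
  because one parameter controls the skewness ($2/\sqrt{k}$) and the
  moments are closed-form; any right-skewed family would emulate the
  reported uptake shape. Defaults use $k \in \{4, 16, 1\}$ for the
  pelvis/thigh/lower-leg muscle respectively, with mean SUVs of
  0.85/0.64/1.50 g/mL, the magnitudes typical of walking studies.
* **Clusters** — spherical blobs (default two per muscle, radius 6 mm,
  amplitude 3) multiply the background inside them, creating genuinely
  aggregated hot regions; blob voxel sets are recorded as ground truth.
* **Asymmetry** — after generation, the non-dominant muscle's voxels are
  rescaled so that the SI computed on realized pre-smoothing means
  equals the muscle's target SI *exactly*; smoothing is mean-preserving
  in the interior, so the measured SI deviates only through boundary
  effects and noise (recovered within +-3 points in the tests). In the
  default multi-subject study the per-subject targets are drawn from
  centered normals with per-segment spreads of 22/8/60 percentage
  points, reproducing the segment pattern of walking studies —
  near-symmetric thighs, highly variable lower legs (median |SI| of
  roughly 15 %, 5 % and 40 %).
* **Smoothing** — a separable Gaussian with 3 mm FWHM
  ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2} \approx 1.274$ mm, converted
  to voxels per axis), truncated at $4\sigma$ and renormalized, with
  border rows renormalized again so constant fields are preserved. This
  emulates scanner post-filtering; it is applied after blob injection,
  matching the acquisition order.
* **Acquisition** — defaults of 53.6 MBq injected, 60 min uptake time,
  F-18 half-life, 70 kg body mass; the fixture generator draws body mass
  uniformly from 55.5-91.7 kg and dose from N(53.6, 1.8) MBq per
  subject.

All randomness flows from a single integer seed; the same spec yields a
bit-identical study, and the study driver's outputs are byte-identical
across reruns.

**What the phantom does *not* emulate** — and hence what passing tests
do not demonstrate about clinical data: no anatomy (ellipsoids, not
muscles), no PET count noise (Poisson sinogram noise, scatter, randoms),
no attenuation or reconstruction artifacts, no partial-volume effect
beyond Gaussian smoothing, no registration error between mask and
volume, and no within-scan decay gradient across bed positions (a single
global decay correction is applied; the per-bed handling of the original
acquisition chain is not reconstructable from its description).
Ground-truth recovery on phantoms validates the *estimators*, not the
acquisition.

## Numerical and design choices

* Voxel membership is binary (label equality); extraction order is R's
  array linear order (x fastest), fixed and documented, so tie-breaks
  and outputs are deterministic.
* Hot-count rounding is half-up (`floor(x + 0.5)`), not banker's
  rounding, so e.g. a 50-voxel ROI gets 3 hot voxels, keeping the
  realized fraction nearest 5 %.
* The exact signed-rank enumeration is computed by convolving the
  distribution of the doubled midranks (integers), not by expanding
  $2^n$ patterns; an explicit pattern-enumeration oracle verifies
  equality in the tests for $n \le 12$.
* When the cold NHN mean is zero while the hot mean is positive (one
  solid hot component not touching any cold voxel) the index is reported
  as `Inf` with a flag; when both are zero it is `NaN`, flagged.
* Degenerate inputs are errors, not silent NAs: empty ROIs, constant
  input to skewness, both limbs zero in SI, n < 3 in the KS screen.
* Quartiles and box-plot summaries use R's default type-7 linear
  interpolation with the 1.5 IQR outlier rule, the convention of the
  figures this package's tables mirror.
* Study configs are plain-text YAML rather than an ad-hoc key/value
  format, because a mature, strict parser is available; every referenced
  path is resolved and checked before any computation starts.
* DICOM series are not read directly: no maintained R DICOM reader is
  available to build on, and scanner exports are routinely converted to
  NIfTI by standard tools that preserve the rescale slope/intercept —
  which this package then applies explicitly (`applyRescale()`,
  `decayCorrectActivity()`).

## Worked example

```{r example, eval = FALSE}
library(musclePET)

# a 10-subject synthetic study, fully seeded
cfg <- writeFixtureStudy("study", nSubjects = 10, seed = 42)
res <- runStudy(cfg, outputDir = "study/results")

res$asiSummary        # median/range ASI per muscle, subjects > 25 %
res$uptakeSummary     # SUV/AUV medians per limb with signed-rank p-values
res$clusterSummary    # box-plot statistics of the cluster index

# one muscle in depth
vol  <- readVolume("study/S01/volume_dominant.nii.gz")
mask <- readLabelMask("study/S01/mask_dominant.nii.gz")
ca   <- clusterAnalysis(vol, mask, label = 3, nPermutations = 200,
                        seed = 1)
ca$clusterIndex; ca$pPerm
```

## Known limitations

* Only body-mass SUV is implemented (no lean-body-mass or BSA variants).
* The five-largest-muscles-per-segment selection uses measured volumes
  with name-order tie-breaks; exclusion rules beyond "missing limb" are
  not modeled.
* The permutation null shuffles hot flags uniformly, which calibrates
  spatial aggregation only; it does not model spatially correlated
  noise, so on strongly smoothed data even homogeneous fields show mild
  aggregation relative to that null (the smoothing kernel itself
  clusters ranks). Interpret the index against phantoms with matched
  smoothing, as the tests do.
* 18- and 26-connectivity variants are deliberately absent from the
  default pathway.
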