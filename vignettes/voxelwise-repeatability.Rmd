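---
title: "Assessing voxel-wise radiomics repeatability and habitat robustness"
author: "habitatlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing voxel-wise radiomics repeatability and habitat robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatlab)
```

## The problem

Conventional ("VOI-wise") radiomics reduces a segmented lesion to one
number per texture feature. Voxel-wise (3D) radiomics instead slides a
small cubic kernel over every voxel of the lesion and evaluates the
feature inside each kernel, producing a *feature map* — the input for
spatial analyses such as imaging habitats (clusters of voxels sharing a
radiological phenotype). A feature map has far more exposure to noise and
misalignment than a whole-lesion average, so before habitats computed from
such maps can be trusted, two questions must be answered per feature:

* **Repeatability** — if the same lesion is scanned twice minutes apart,
  how well do the two maps agree voxel by voxel?
* **Reproducibility** — how stable are maps and feature rankings under the
  extraction parameters (intensity bin width `B`, kernel radius `R`)?

`habitatlab` implements the full assessment chain on synthetic CT-like
lesion phantoms with known ground truth: phantom simulation, retest and
perturbation-surrogate generation, voxel-wise GLCM extraction, map
agreement metrics, feature classification, and habitat-robustness scoring.

## Synthetic test–retest phantoms

`phantomSpec()` / `generatePhantom()` build an ellipsoidal lesion embedded
in a lung-like background (default −800 HU), partitioned into `kTrue`
concentric ellipsoidal shells. Shells are used as the ground-truth habitat
geometry because they give a deterministic, unambiguous label partition
for Dice/ARI scoring (a seeded Voronoi alternative would introduce its own
sampling variability). Each shell has:

* a mean attenuation (`regionMeansHu`), the dominant contrast between
  habitats;
* a correlated Gaussian texture field: white noise smoothed with a
  Gaussian kernel of SD `regionCorrLenMm` and renormalised to SD
  `regionTextureHu`. Distinct amplitudes and correlation lengths per shell
  are what make habitats distinguishable by *texture*, not just by mean —
  emulating, e.g., homogeneous necrotic cores versus heterogeneous solid
  rims.

Acquisition noise is added everywhere, with SD `noiseSigmaHu` and spatial
correlation length `noiseCorrLenMm`. The correlation matters: CT noise is
not white (the reconstruction point-spread function correlates it, and
resampling a real scan to the 1 mm analysis grid correlates it further).
With white noise at typical CT amplitudes, neighbouring voxels would fall
~2 bins apart at `B = 12` HU and every kernel co-occurrence matrix would
saturate into featureless jitter — a failure to emulate the acquisition
being modelled, visible as entropy-family maps carrying no spatial signal.
The noiseless object is likewise imaged through the PSF (`psfMm`), so
lesion-boundary voxels mix lesion and lung values in *every* scan — the
partial volume any real acquisition has. Without it, only resampled
(retest) scans would show boundary mixing, and the min-anchored
discretization would shift between the scans of a pair.

The retest scan (`generateRetest()`) is the test image pushed through a
small rigid transform (sub-voxel shifts, a few degrees of axial rotation)
with order-3 B-spline interpolation plus *independent* acquisition noise,
modelling two acquisitions minutes apart. The applied transform is
recorded, and `alignRetest()` resamples back — so a "registered" pair
carries realistic interpolation/registration residuals, exactly the error
a rigid registration of real scans leaves behind.

Phantoms are deterministic given (spec, seed): regenerating with the same
seed reproduces the volume bit for bit.

## Perturbation surrogates

When no retest scan exists, a perturbed copy of the test scan can stand in
for it. `makeSyntheticRetest()` applies an ordered chain of:

* **N** — Gaussian noise with SD estimated from the image itself
  (`estimateNoiseSigma()`: single-level 3D Haar transform, diagonal detail
  band, `median(|d|)/0.6745` — robust to smooth structure);
* **T** — translation by a fraction `eta` of the voxel spacing per axis;
* **R** — rotation by `theta` degrees about the through-slice axis.

Defaults are a single low-magnitude perturbation of each kind
(`eta = (0.25, 0.25, 0.25)`, `theta = 5°`, noise auto-estimated), exposed
in configuration and recorded in reports, never hard-coded in logic. The
mask is *not* perturbed: comparisons use the original contour at the
original indices.

## Voxel-wise GLCM feature maps

`computeFeatureMaps()` evaluates, at every in-mask voxel, the 23 supported
gray-level co-occurrence features (the maximal correlation coefficient is
not supported) over the cubic kernel of edge `2R + 1`:

* Intensities are discretized once, globally, with fixed bin width:
  `g(x) = floor((x − min_mask)/B) + 1`, anchored at the in-mask minimum
  and applied to the whole padded crop. A global table keeps the gray
  axis (and the `Ng` appearing in Idn/Idmn denominators) identical across
  kernels, and makes maps invariant to global intensity shifts.
  Out-of-mask voxels are clamped into `[1, Ng]`.
* The GLCM is accumulated symmetrically (each pair in both orders) for
  each of the 13 unique 3D direction offsets at distance 1 voxel; features
  are computed per direction and averaged over the directions that contain
  at least one pair. A merged-matrix mode is not used for maps (averaging
  is the extraction-tool convention the assessment mirrors).
* By default the kernel draws on *all* voxels of the padded crop (the
  padding exists precisely so boundary kernels are full);
  `maskedKernel = TRUE` restricts both pair endpoints to the mask. Both
  modes are first-class because published pipelines differ here.
* Entropies use base-2 logarithms with `eps = 2.2e-16` inside the log;
  the Imc2 exponent argument is clamped at 0 before the square root.
  Degenerate single-level matrices follow fixed conventions (entropy 0,
  joint energy 1, maximum probability 1, Imc1 0, Imc2 0, correlation 1);
  a kernel with no valid pairs in any direction yields 0 for every
  feature and is flagged.

The compiled extractor is verified against an independent naive
re-extraction (a fresh mask-wide R-implemented GLCM per voxel) to 1e-10,
and against hand-enumerated small patches. `voiFeatures()` computes the
conventional whole-lesion values with one mask-wide GLCM.

Paired maps are normalized to the unit interval *jointly* (one affine map
per feature over the union of both in-mask ranges). Per-pair rather than
per-map normalization is the default because an independent per-map
min–max would force both maps onto [0, 1] separately and the gamma
criterion's `F_max` reference would no longer see genuine scale
differences between the scans.

## Agreement metrics

* `ccc()` — Lin's concordance (population moments), penalising both
  decorrelation and location/scale shift; `pcorr()` — Pearson correlation.
  Conventions: both-constant-and-equal ⇒ 1; single constant input ⇒ 0.
* `ssim3d()` — mean local structural similarity in a cubic window (default
  edge 7, clipped at the crop boundary), constants `C1 = (0.01 L)²`,
  `C2 = (0.03 L)²` with `L = 1` on normalized maps.
* `gammaMap()` — the radiotherapy gamma index transplanted to feature
  maps: for each reference voxel, the minimum over nearby sample positions
  of the root-sum-square of (spatial distance / DTA) and (feature
  difference / ΔF), with ΔF a percentage of the reference map's in-mask
  maximum (`F_max` on the *reference* side — the global-gamma convention).
  The evaluated map is sampled on a trilinearly upsampled sub-voxel
  lattice (default ×3); candidate offsets are visited in increasing
  distance so the search terminates once the distance term alone exceeds
  the current minimum. The default search cap of 3 × DTA is safe because
  beyond it the distance term alone is ≥ 3; voxels with no valid sample in
  range are marked invalid and excluded from the passing-rate denominator.
  `gammaPassingRate()` reports the percentage of valid in-mask voxels with
  Γ < 1. The default criterion is 2 mm / 1 %.
* `dsc()` / `meanDsc()` — per-label Dice and its unweighted mean over the
  labels present in at least one map; an optional exhaustive permutation
  matching serves externally produced label maps whose identities do not
  correspond.

`rankFeatures()` classifies features by fixed thresholds — median CCC
strictly above 0.9, median gamma passing rate strictly above 95 % — with
deterministic ordering (ties broken alphabetically). No hypothesis tests
or multiplicity control are involved; the classification is by design a
thresholding of medians.

## Imaging habitats

`buildFeatureMatrix()` assembles the in-mask voxels (fixed raster order)
by selected features (all 23, the nine-feature robust subset, or an
explicit list), pair-normalized. `computeHabitats()` runs PCA (columns
centred, no scaling, no whitening; components retained by count — default
5 — rather than by a variance threshold) and K-means on the leading
scores. In the default *pooled* mode the test and retest rows are
clustered jointly, so cluster identities correspond between scans by
construction — no post-hoc label matching is needed; a fit-on-test mode
(retest rows projected and assigned to nearest centroid) is the
alternative. K-means uses `stats::kmeans` with 10 seeded random starts
(maximum 300 iterations); with 10 restarts on a handful of well-populated
components this is as reliable as a k-means++ initialisation at these
problem sizes, and fully reproducible. Lesion-level robustness is the
unweighted mean Dice over habitat labels.

## The experiment pipeline

`experimentConfig()` + `runExperiment()` orchestrate the full design:
simulate a cohort of phantoms (per-lesion seeds and small semi-axis
jitters derived from one master seed), generate aligned retests and
perturbed surrogates, extract maps at the fixed combination (default
`B = 12`, `R = 1` — the combination used for the repeatability and
perturbed arms), compute agreement tables, rank features, optionally run
the full `B × R` reproducibility grid, and score habitat robustness for
each `k` and feature selection. `enumerateTasks()` lists every extraction
task of a design up front; re-running a configuration reproduces every
output byte for byte, and the manifest records a configuration hash.

## Default study conditions

The package-default synthetic cohort used by the acceptance script and the
heavier tests: 10 phantoms on a 44³ grid at 1 mm, lesion semi-axes around
(10, 9, 8) mm (jittered ±15 % per phantom), three shells with means
(−60, 5, 70) HU, texture amplitudes (10, 50, 90) HU and correlation
lengths (1.5, 2.5, 3.5) mm increasing from core to rim (a homogeneous
core and an increasingly heterogeneous periphery), lung background at
−800 HU, a 0.6 mm object PSF, acquisition noise of 20 HU with 0.8 mm
correlation length; retest motion of ~0.4 mm shifts and 3° axial rotation
with independent noise, aligned back through the known transform
composed with a ~0.4 mm / 0.5° registration residual; perturbation
defaults as above. These sizes keep a full cohort
run in minutes on one core while leaving ≥ 1000 voxels per lesion; they
are plausibility choices for unenhanced thoracic CT, not a calibration to
any specific cohort.

## What the phantoms do and do not show

The generator reproduces the *mechanisms* the assessment needs — paired
acquisitions differing by rigid motion, independent correlated noise,
registration residuals, habitat-structured texture — with known ground
truth. It does not reproduce scanner physics (beam hardening,
reconstruction kernels), respiratory deformation, contour variability
(contours are shared by construction), or the intensity statistics of any
particular cohort. Passing results therefore validate the pipeline's
correctness and the *direction* of its findings (e.g. which feature
families are more repeatable; that restricting habitats to robust
features increases their stability), not the numeric values any real
cohort would produce.

## Numerical choices and edge cases

* Resampling uses the standard recursive B-spline prefilter (pole
  √3 − 2, mirror boundaries, 1e-12 init tolerance); out-of-field samples
  replicate the nearest edge rather than injecting artificial air values
  into the padded crop. Masks are resampled nearest-neighbour, never
  smoothed.
* `resampleIsotropic()` is an exact identity when the grid already has the
  target spacing, making it idempotent on the grid.
* The crop pad defaults to 10 mm (a conventional extraction-tool default),
  `ceil(pad/spacing)` voxels per side, clamped at the image faces.
* CCC/PCORR/SSIM use population (divide-by-n) moments throughout.
* All randomness flows through explicit seeds; child seeds are derived
  from the master seed and kept below 2³¹.

## A worked example

```{r example, eval = FALSE}
ph <- generatePhantom(phantomSpec(seed = 7))
retest <- alignRetest(generateRetest(ph$image, rigidMotionSpec(),
                                     seed = 8, mask = ph$mask))
crop <- cropToLesion(ph$image, ph$mask)
cropR <- cropToLesion(retest, ph$mask)$image

params <- extractionParams(binWidth = 12, kernelRadius = 1)
mapsT <- computeFeatureMaps(crop$image, crop$mask, params, "test")
mapsR <- computeFeatureMaps(cropR, crop$mask, params, "retest")
agreementTable(mapsT, mapsR, crop$mask, "phantom07")

out <- habitatRobustness(crop$image, cropR, crop$mask, params,
                         habitatConfig(k = 3, featureSelection = "robust"))
out$meanDsc
```

## Known limitations

* Lesion ground truth is geometric (shells); real habitats are irregular,
  so absolute Dice values here are optimistic relative to clinical data.
* The gamma search interpolates the evaluated map trilinearly on a finite
  sub-voxel lattice; Γ is an upper bound on the continuous-interpolation
  minimum (tightening with the upsample factor).
* Feature maps near the lesion boundary mix lesion and background content
  in the default unmasked-kernel mode; use `maskedKernel = TRUE` to
  confine the analysis strictly to the segmentation.
* Only GLCM features are implemented; first-order, shape and other texture
  families (and filtered inputs) are out of scope, as is the maximal
  correlation coefficient.
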