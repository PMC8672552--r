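---
title: "Methods: delta radiomics for MR-guided radiotherapy"
author: "DeltaRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta radiomics for MR-guided radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model each
stage implements, the numerical conventions, the parameters that
matter, what the synthetic generator does and does not emulate, and the
design choices made where the design was genuinely open.

## Setting and data model

A patient contributes six grid-aligned 3D MR volumes — a simulation
scan (`SIM`) acquired before treatment and one scan immediately before
each of five SBRT fractions (`F1`–`F5`) — at a fixed voxel size
(default 1.5 × 1.5 × 3 mm), together with a gross tumor volume (GTV)
contour, a kidney contour, and a survival record (PFS days, event
indicator). The six scans are required to share one grid: online rigid
registration is performed by the treatment system and is declared a
preprocessing responsibility, so the package never resamples or
interpolates intensities. Voxel centers sit at `index * spacing`
(0-based indices), and the contour rasterizer marks a voxel foreground
iff its in-plane center is inside the slice polygon under the even-odd
rule.

## Intensity normalization

Balanced-SSFP signal has no absolute scale, and session-to-session
global intensity drift is of the same order as any biological change.
Each scan is therefore divided by its own median kidney signal,
measured on exactly three axial slices at ¼, ½ and ¾ of the kidney's
slice extent (rounding half away from zero; a single-slice kidney uses
that slice three times). Division makes the result exactly invariant to
any global multiplicative rescaling of the raw scan — the property the
test suite checks to 1e-12 relative tolerance. Median convention
throughout: the mean of the two central order statistics for even
counts.

The *drift analysis* quantifies why this matters: for each patient the
F1/SIM ratio of median GTV signal is compared with the same ratio over
an automatically derived abdomen cross-section (the 10 slices centered
on the GTV's lower-median slice, Otsu-thresholded, largest connected
component, per-slice hole filling, GTV voxels removed). Before
normalization the two ratios correlate strongly across patients —
apparent tumor change is mostly shared technical drift; after
normalization the correlation is gone. Pearson's r with a two-sided
t-test (n − 2 df) is reported. The abdomen ROI excludes only the GTV
(not the kidney); the thresholding recipe is this package's
parameter-free choice, as no standard exists for this step.

## Feature extraction

Features are computed on the GTV after discretizing ROI intensities
into `nBins = 64` equal-width bins spanning the ROI's own [min, max]
(fixed-bin-number). Consequences worth knowing:

* every feature is invariant under monotone affine transforms of the
  raw signal, so feature values do not depend on the normalization
  constant;
* the minimum and maximum bin labels are 1 and 64 for any
  non-constant ROI, so those two histogram features are constants of
  the method; a constant ROI maps to label 1 by convention.

The registry has 73 features: 11 histogram features computed on bin
labels (mean, variance, skewness, excess kurtosis, median, min, max,
10th/90th percentile by nearest rank, entropy in bits, uniformity;
population 1/n moments; zero-variance ROIs take skewness = kurtosis =
0), and 62 texture features. Texture matrices are built in 3D over the
13 unique Chebyshev-distance-1 directions in voxel units (no distance
weighting, consistent with never interpolating), merged across
directions before feature computation:

* **GLCM** (25 features): symmetric, direction-merged, normalized.
  The maximal correlation coefficient is excluded as numerically
  fragile, which lands exactly on the canonical 25-feature list. A
  single-level ROI is a point mass: contrast 0, angular second moment
  1, correlation 1 by convention; an ROI with no valid voxel pair
  yields `NA` features with a warning.
* **GLRLM** (16): runs of equal labels along each direction, pooled;
  out-of-ROI voxels break runs. Because runs are pooled over 13
  directions, run percentage is `N_runs / (13 · N_voxels)`, so an ROI
  in which every run has length 1 scores exactly 1.
* **GLSZM** (16): zones are 26-connected equal-label components
  (direction-free; zone percentage is `N_zones / N_voxels`).
* **NGTDM** (5): per-level summed absolute difference from the mean of
  valid 26-neighbours; coarseness capped at 1e6 when its denominator
  is 0 (e.g. a single-voxel ROI).

Each builder is verified against an independent brute-force enumerator
(pair counting, line walking, flood fill, neighbourhood averaging) on
hundreds of random small arrays — exactly, not approximately.

## Delta features and the survival screen

Imaging change is the ratio of each feature at the last versus first
fraction, F5/F1, computed per patient in registry order. A zero
denominator yields `NaN` for that feature only. Ratios are plain signed
division: for sign-crossing features (skewness, cluster shade) a sign
flip makes the ratio non-monotone in the underlying change. This is a
real limitation of ratio-based delta radiomics — near-symmetric
baseline histograms put the ratio in a division-by-near-zero regime —
and it is why the generator keeps baseline skewness bounded away from
zero (below).

Each feature ratio is screened against PFS with a univariate Cox
proportional-hazards fit (Efron tie handling; Wald tests and CIs on the
log scale). Holm's step-down correction is applied separately within
the histogram family (m = 11) and the texture family (m = 62), treating
the two families as separate hypothesis sets, mirroring a two-stage
screening design. Significant features proceed to risk stratification:
every midpoint between consecutive sorted unique covariate values with
at least `minGroup = 5` patients on each side is scored by the
two-sample log-rank statistic; the maximizing threshold defines high
(above) and low (below) risk groups. Because the threshold is
optimized, the naive log-rank p at the chosen cut is anticonservative;
significance of the maximal statistic is assessed by permuting the
covariate (`nPerm` label permutations, default 9999, seeded;
p = (1 + #{perm ≥ obs}) / (1 + nPerm)). This is the decision surface of
a single-split conditional inference tree; full recursive tree
machinery is deliberately out of scope since one threshold is the
object of interest. Kaplan–Meier curves and the standard two-sample
log-rank test summarize the resulting groups, and RECIST 1.1
classification (≥ +20% progressive disease, ≤ −30% partial response,
boundaries inclusive) is provided for local-response bookkeeping.

The null behaviour of the split is part of the test suite: over
hundreds of null replicates the type-I error at α = 0.05 stays near
nominal.

## Spatial stability

Contouring is the dominant operator-dependent step, so each feature's
robustness is measured by re-extracting all 73 features on the SIM scan
with the GTV eroded and dilated per slice by a disk of radius 1.5 mm —
one pixel at the native in-plane spacing, where the disk degenerates to
the 4-connected cross. Morphology is strictly 2D: the ROI's slice
extent never changes. Per feature, Lin's CCC (population moments) is
computed between the original-ROI values and each perturbed-ROI values
across patients, and the two pairwise coefficients are averaged; a
multi-rater overall CCC is available behind `method = "overall"`. The
averaging choice is documented rather than claimed standard — how two
pairwise comparisons become one number is not specified by the CCC
itself. Identical measurement vectors count as perfect agreement
(CCC 1) even for features that are constant across patients, where the
raw formula is 0/0; `linCCC` itself returns `NaN` with a warning in
that degenerate case. Patients whose GTV vanishes under erosion are
excluded and listed. Translation of the ROI is available as an
additional perturbation mode in `perturbRoi` but is not part of the
default stability protocol.

## The synthetic cohort generator

The generator exists so that every stage has a ground truth. Each
patient gets an elliptical body, an ellipsoidal kidney of constant true
intensity 1, and an ellipsoidal GTV (~1000 voxels at the default
64 × 64 × 24 grid) whose intensities are drawn from a shifted-gamma
(Pearson III) law with mean 0.8, SD 0.15 and a target skewness that
moves linearly from the baseline at F1 to the group target at F5
(SIM shares the baseline). Shifted gamma was chosen over a skew-normal
because its skewness `2/√shape` is unbounded — per-patient F5 targets
can exceed 1.5, beyond the skew-normal's ~0.995 ceiling — and its
closed-form moments give the truth oracle. A one-voxel partial-volume
shell around the GTV mixes tumor and body signal 50/50, emulating the
fuzzy tumor boundary without which a 1.5 mm dilation would sample pure
surrounding tissue and no feature could be spatially stable.

Per scan, the whole volume is multiplied by a global drift factor
`exp(N(0, driftSd²))` (default 0.2), tumor and body additionally
receive small independent per-session factors (`bioSd = 0.03`) —
without them, post-normalization signal ratios would differ only by
measurement noise and the shared kidney-median estimate would induce a
spurious between-region correlation — and additive Gaussian noise
(`noiseSd = 0.02`) is applied. PFS is exponential with hazard
`baselineHazard · exp(beta · ratio)` on the *true* skewness ratio
(default `beta = log(2.75)`, baseline 0.0012/day), under independent
exponential censoring whose rate is calibrated so the expected event
fraction matches `eventFraction = 0.6`.

Skew parameters: the latent groups target F5/F1 skewness ratios of
1.52 (high risk) and 0.60 (low risk) around a mean baseline skewness of
0.60. The between-patient spreads are a design choice: quoted
uncertainties of cohort summaries of this kind cannot be between-patient
SDs (single-measurement sampling noise at ~1000 voxels is already
~0.08), so substantial heterogeneity is used (baseline SD 0.25, ratio
SDs 0.15/0.04), truncating baseline skewness at ≥ 0.15 so the ratio
covariate never enters the division-by-near-zero regime. The price is
that the generator does not emulate near-symmetric tumors — precisely
the case in which a skewness *ratio* endpoint is ill-defined; that case
is a documented limitation of the endpoint itself.

Two named configurations are used by the tests and the acceptance
script:

* `syntheticConfig(nPatients = 26, ...)` — the study-scale emulation.
  At this scale a single cohort is frequently *not* significant after
  Holm: with ~16 events and a hazard ratio of 2.75 per ratio unit the
  screen is near the edge of its power, which is a faithful property of
  the emulated conditions, not a defect.
* `strongEffectConfig()` — the machinery-validation configuration
  (n = 100, hazard ratio 6 per unit, well-resolved baselines with mean
  skewness 1.0 and minimum 0.5, tight within-group ratio spreads
  0.05/0.02). End-to-end recovery — the skewness ratio flagged after
  Holm and the split threshold inside the latent groups' ratio gap — is
  asserted at this configuration over seeded replicates.

What the generator does not emulate: MR physics (bSSFP contrast, bias
fields), organ motion and registration error, spatially structured
tumor texture (voxels are exchangeable within the ROI, so
between-patient texture contrast is weaker than in real tumors),
multi-center protocol variation, and near-symmetric baseline
histograms. Passing tests therefore demonstrate correctness of the
computational chain under controlled conditions, not clinical validity
on real images.

## Numerical conventions and degenerate inputs

* Rounding of slice fractions and pixel radii: half away from zero
  (R's `round` is banker's rounding and is not used there).
* Median: mean of central pair; GTV median slice: lower median.
* Percentiles (histogram p10/p90): nearest-rank order statistic.
* Zero-variance ROI: skewness = kurtosis = 0; GLCM correlation = 1.
* NGTDM coarseness capped at 1e6 when its denominator is 0.
* Erosion that empties every slice raises an error and excludes the
  patient from stability with a logged reason.
* `bestSplit` ties: `which.max` takes the first (lowest) maximizing
  midpoint.
* All cohort processing iterates patients in sorted id order; reruns
  with the same inputs, configuration and seed produce byte-identical
  CSVs.

## Problem sizes used in the checks

The test suite runs cohorts of 3–30 patients on 32 × 32 × 12 grids for
unit-level properties, 30 patients at the default grid for the drift
property (five cohorts, medians of r), 500 subjects for Cox recovery,
500 replicates for the null calibration of the split, and 20 seeded
replicates of n = 100 strong-effect cohorts for end-to-end recovery —
sizes chosen so each check is statistically decisive for the property
it tests.

## Interfaces

Cohorts are exchanged as NIfTI volume/mask files plus a survival CSV
(the canonical layout, written by `writeCohort`), or as minimal
explicit-VR little-endian DICOM series with contours supplied as JSON
polygon files and rasterized by `rasterizeContours`; the package's
supported contour interchange is the polygon list, not the RT-Structure
sequence encoding. Feature tables round-trip through CSV at 15
significant digits. The feature registry ships as
`inst/extdata/feature_registry.json`.
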