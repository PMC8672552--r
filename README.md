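# DeltaRadiomics

Delta-radiomics analysis of longitudinal MR-guided radiotherapy (MRgRT)
imaging, built for the setting where a patient is scanned on a 0.35T
MRI-Linac at simulation (SIM) and before each of five SBRT fractions
(F1–F5), and the question is whether the *change* in tumor image
features over treatment predicts progression-free survival (PFS).

MR signal intensities carry no absolute units, so raw longitudinal
comparisons are dominated by technical session-to-session scaling. The
pipeline therefore:

1. **Normalizes** every scan by its median kidney signal, measured on
   three slices at ¼, ½ and ¾ of the kidney's slice extent — after
   division, global multiplicative drift cancels exactly.
2. **Extracts 73 standardized radiomic features** from the gross tumor
   volume (GTV) at 64 fixed intensity bins: 11 intensity-histogram
   features and 62 texture features (25 GLCM, 16 GLRLM, 16 GLSZM,
   5 NGTDM), with all texture matrices aggregated in 3D over the 13
   unique voxel directions.
3. **Forms delta features** — the ratio of each feature at the last
   versus the first fraction, `Δf = f(F5) / f(F1)` — as the measure of
   imaging change.
4. **Screens each ratio against PFS** with univariate Cox proportional
   hazards (Efron ties), Holm-corrected separately within the histogram
   and texture families, and stratifies patients by a maximally selected
   log-rank threshold whose significance is assessed by permutation
   (the single-split decision surface of a conditional inference tree).
5. **Quantifies spatial robustness** of every feature by re-extracting
   it on per-slice ±1.5 mm eroded/dilated GTV contours and summarizing
   agreement with Lin's concordance correlation coefficient (CCC),

   `CCC = 2·cov(x, y) / (var(x) + var(y) + (mean(x) − mean(y))²)`.

A synthetic cohort generator (`generateCohort`) builds grid-aligned
phantom studies — elliptical body, constant-intensity kidney,
shifted-gamma tumor intensities with a controlled skewness trajectory,
per-scan global drift, and survival drawn from a proportional-hazards
model on the true skewness ratio — so every stage is testable with known
ground truth and no patient data.

## Worked example

```r
library(DeltaRadiomics)

cohort <- generateCohort(syntheticConfig(nPatients = 26, seed = 7))
studies <- cohort$studies
studies[[1]]
#> PatientStudy 'pt001': 6 scans (SIM F1 F2 F3 F4 F5), GTV 1046 voxels, kidney 514 voxels
#>   PFS 17 days, event = 0

driftAnalysis(studies, normalized = FALSE)
#> DriftReport (raw): n = 26 patients, Pearson r = 0.982, p = 7.01e-19
```

Before normalization the tumor's apparent SIM→F1 signal change is
almost entirely the global technical drift shared with the rest of the
abdomen (r = 0.98); after kidney-median normalization the correlation
disappears (`driftAnalysis(studies, normalized = TRUE)`).

```r
delta <- buildDeltaTable(studies)
delta
#> DeltaFeatureTable: 26 patients x 73 features (F5 / F1, kidney_median normalization, 64 bins)

stab <- stabilityReport(studies)
stab
#> StabilityReport (mean_pairwise, +/-1.5 mm on SIM): 73 features
#>   median CCC GLCM       0.852
#>   median CCC GLRLM      0.709
#>   median CCC GLSZM      0.724
#>   median CCC histogram  0.877
#>   median CCC NGTDM      0.454
```

Histogram features (including skewness, CCC 0.861 here) tolerate
±1.5 mm contour perturbation much better than run-length or NGTDM
features — the basis for preferring them in small-cohort modeling. At
this emulated study scale (26 patients) a single cohort is underpowered
for the survival screen; on a larger cohort with a strong effect the
full chain resolves cleanly:

```r
cohort <- generateCohort(strongEffectConfig(nPatients = 100, seed = 7))
delta <- buildDeltaTable(cohort$studies)
surv <- do.call(rbind, lapply(cohort$studies, survivalRecord))
screen <- coxScreen(delta, surv)
subset(screen, feature == "hist_skewness")
#>        feature    family hazard_ratio ci_low ci_high    p_raw p_adjusted
#>  hist_skewness histogram         2.24   1.51     3.3 5.22e-05    0.00047

sv <- surv[match(rownames(deltaValues(delta)), surv$patient_id), ]
bestSplit(deltaValues(delta)[, "hist_skewness"], sv$pfs_days, sv$event,
          nPerm = 999, seed = 7)
#> RiskSplit: threshold 1.026 (high: 53, low: 47), max chi-sq 26.12, permutation p = 0.002
```

A skewness ratio above ~1 (skewness rising over treatment) marks the
high-risk group; the threshold sits in the gap between the two latent
groups' true ratios (1.52 vs 0.60).

`runPipeline()` chains all stages and writes the delta table, screen,
stability report, risk groups, a run log and a hashed manifest;
`inst/scripts/mrgrt_pipeline.R` wraps it for the shell. Cohorts are read
from NIfTI volume/mask layouts or minimal DICOM series (with JSON
contour polygons rasterized by `rasterizeContours`).

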