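test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- syntheticConfig(nPatients = 3, dims = c(24, 24, 10), seed = 61)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$truth, b$truth)
  for (id in names(a$studies))
    for (lb in names(scans(a$studies[[id]])))
      expect_identical(voxels(scans(a$studies[[id]])[[lb]]),
                       voxels(scans(b$studies[[id]])[[lb]]))
  expect_error(syntheticConfig(nPatients = 5), "seed")
  expect_error(syntheticConfig(nPatients = 2, seed = 1), ">= 3")
})

test_that("without drift the kidney median is stable across scans", {
  coh <- generateCohort(syntheticConfig(nPatients = 3, dims = c(32, 32, 12),
                                        driftSd = 0, seed = 62))
  for (st in coh$studies) {
    med <- vapply(scans(st), function(v) kidneyMedian(v, kidney(st)),
                  numeric(1))
    expect_lt(max(abs(med - 1)), 0.02)
  }
})

test_that("a zero-noise cohort has kidney median exactly drift times unit intensity", {
  coh <- generateCohort(syntheticConfig(nPatients = 3, dims = c(32, 32, 12),
                                        noiseSd = 0, seed = 63))
  tc <- truthCheck(coh$studies, coh$truth)
  expect_lt(tc$maxKidneyDev, 1e-12)
})

test_that("realized tumor skewness tracks the generator's targets", {
  # cohort mean recovery on many small-ROI patients
  coh <- generateCohort(syntheticConfig(nPatients = 60, dims = c(32, 32, 12),
                                        noiseSd = 0, driftSd = 0, seed = 64))
  tc <- truthCheck(coh$studies, coh$truth)
  f1 <- tc$perScan[tc$perScan$scan == "F1", ]
  truthMean <- mean(coh$truth$skew_f1)
  expect_lt(abs(mean(f1$empirical_skew) - truthMean), 0.1)

  # shifted-gamma moments: empirical mean of GTV intensities matches
  st <- coh$studies[[1]]
  x <- voxels(scans(st)$F1)[voxels(gtv(st))]
  expect_lt(abs(mean(x) - 0.8 * coh$truth$drift_F1[1]), 0.05)

  # groups separate in the true ratio
  expect_gt(min(coh$truth$skew_ratio[coh$truth$group == "high"]),
            max(coh$truth$skew_ratio[coh$truth$group == "low"]))

  # per-scan deviations stay within sampling error at the default ROI size
  cohBig <- generateCohort(syntheticConfig(nPatients = 12, seed = 68))
  tcBig <- truthCheck(cohBig$studies, cohBig$truth)
  expect_lt(tcBig$maxSkewDev, 0.6)
})

test_that("censoring calibration yields roughly the configured event fraction", {
  coh <- generateCohort(syntheticConfig(nPatients = 400,
                                        dims = c(16, 16, 8),
                                        eventFraction = 0.6, seed = 65))
  expect_gt(mean(coh$truth$event), 0.5)
  expect_lt(mean(coh$truth$event), 0.7)
})

test_that("truthCheck demands matching patient ids", {
  coh <- generateCohort(syntheticConfig(nPatients = 3, dims = c(24, 24, 10),
                                        seed = 66))
  bad <- coh$truth
  bad$patient_id <- paste0("x", bad$patient_id)
  expect_error(truthCheck(coh$studies, bad), "ids")
})

test_that("generated studies pass through the NIfTI layout unchanged", {
  coh <- generateCohort(syntheticConfig(nPatients = 3, dims = c(24, 24, 10),
                                        seed = 67))
  dir <- withr::local_tempdir()
  writeCohort(coh$studies, dir)
  back <- loadCohort(dir)
  expect_identical(names(back), names(coh$studies))
  expect_identical(voxels(scans(back[[2]])$F4), voxels(scans(coh$studies[[2]])$F4))
  expect_identical(voxels(gtv(back[[3]])), voxels(gtv(coh$studies[[3]])))
})
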