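registryVector <- function(fill = 1) {
  setNames(rep(fill, 73), featureRegistry()$name)
}

test_that("identical feature vectors give unit ratios; registry order enforced", {
  fv <- registryVector(2.5)
  expect_true(all(deltaRatio(fv, fv) == 1))
  bad <- fv; names(bad)[1] <- "oops"
  expect_error(deltaRatio(fv, bad), "registry")
})

test_that("a skewness increase of 52% appears as ratio 1.52 regardless of baseline", {
  for (s in c(0.4, 0.6, 1.1)) {
    f1 <- registryVector(); f5 <- registryVector()
    f1["hist_skewness"] <- s
    f5["hist_skewness"] <- 1.52 * s
    expect_equal(unname(deltaRatio(f5, f1)["hist_skewness"]), 1.52,
                 tolerance = 1e-12)
  }
})

test_that("a zero denominator poisons only its own feature", {
  f1 <- registryVector(); f5 <- registryVector(3)
  f1["glcm_cluster_shade"] <- 0
  expect_warning(r <- deltaRatio(f5, f1), "glcm_cluster_shade")
  expect_true(is.nan(r["glcm_cluster_shade"]))
  expect_true(all(r[names(r) != "glcm_cluster_shade"] == 3))
})

test_that("the delta table covers the cohort, is deterministic, and logs exclusions", {
  cohort <- generateCohort(syntheticConfig(nPatients = 5,
                                           dims = c(32, 32, 12), seed = 17))
  dt <- buildDeltaTable(cohort$studies)
  expect_s4_class(dt, "DeltaFeatureTable")
  expect_identical(dim(deltaValues(dt)), c(5L, 73L))
  expect_identical(rownames(deltaValues(dt)), sort(names(cohort$studies)))
  expect_output(show(dt), "5 patients x 73 features")

  dt2 <- buildDeltaTable(cohort$studies)
  expect_identical(deltaValues(dt), deltaValues(dt2))

  # a patient with a broken scan is dropped with a reason, others survive
  broken <- cohort$studies
  broken[[2]]@scans$F5 <- NULL
  expect_warning(dt3 <- buildDeltaTable(broken), "excluding")
  expect_identical(nrow(deltaValues(dt3)), 4L)
  expect_identical(dt3@exclusions$patient_id, names(cohort$studies)[2])
})

test_that("ratios of features are invariant to independent global rescaling of raw scans", {
  cohort <- generateCohort(syntheticConfig(nPatients = 3,
                                           dims = c(32, 32, 12), seed = 19))
  st <- cohort$studies[[1]]
  r1 <- suppressWarnings(buildDeltaTable(list(st)))
  st2 <- st
  st2@scans$F1 <- ImageVolume(voxels(st@scans$F1) * 3.7, spacing(st), "F1",
                              patientId(st))
  st2@scans$F5 <- ImageVolume(voxels(st@scans$F5) * 0.2, spacing(st), "F5",
                              patientId(st))
  r2 <- suppressWarnings(buildDeltaTable(list(st2)))
  expect_equal(deltaValues(r1), deltaValues(r2), tolerance = 1e-9)
})
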