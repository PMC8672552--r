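test_that("fixed-bin-number discretization fills bins uniformly on a ramp and clamps the max", {
  n <- 6400
  vox <- array(seq(0, 1 - 1 / n, length.out = n), c(n, 1, 1))
  d <- discretizeRoi(ImageVolume(vox), ROIMask(array(TRUE, c(n, 1, 1))), 64)
  counts <- tabulate(d$labels[!is.na(d$labels)], 64)
  # the ramp top is the ROI max, so the last bin gains the clamped voxel
  expect_true(all(abs(counts - 100) <= 1))
  expect_identical(max(d$labels, na.rm = TRUE), 64L)

  # constant ROI maps to label 1 by convention
  dc <- discretizeRoi(ImageVolume(array(5, c(4, 4, 1))),
                      ROIMask(array(TRUE, c(4, 4, 1))), 64)
  expect_true(all(dc$labels == 1L))

  # the maximum voxel gets label nBins, never nBins + 1
  vox2 <- array(c(0, 0.5, 1), c(3, 1, 1))
  d2 <- discretizeRoi(ImageVolume(vox2), ROIMask(array(TRUE, c(3, 1, 1))), 4)
  expect_identical(as.vector(d2$labels), c(1L, 3L, 4L))

  expect_error(discretizeRoi(ImageVolume(array(1, c(2, 2, 1))),
                             ROIMask(array(TRUE, c(2, 2, 1))), 1), "nBins")
})

test_that("histogram features follow the moment formulas and degenerate conventions", {
  lab4 <- asDiscretized(array(c(1L, 1L, 1L, 5L), c(4, 1, 1)), 8)
  h <- histogramFeatures(lab4)
  expect_equal(unname(h["hist_skewness"]), 6 / 3^1.5, tolerance = 1e-12)
  expect_equal(unname(h["hist_mean"]), 2)
  expect_equal(unname(h["hist_variance"]), 3)

  # symmetric label distribution has zero skewness
  sym <- asDiscretized(array(c(10L, 20L, 10L, 20L), c(4, 1, 1)), 32)
  expect_equal(unname(histogramFeatures(sym)["hist_skewness"]), 0)

  # constant labels: zero variance/entropy, unit uniformity, conventions
  cst <- asDiscretized(array(3L, c(5, 1, 1)), 8)
  hc <- histogramFeatures(cst)
  expect_equal(unname(hc[c("hist_variance", "hist_entropy",
                           "hist_skewness", "hist_kurtosis")]),
               c(0, 0, 0, 0))
  expect_equal(unname(hc["hist_uniformity"]), 1)

  # percentiles use the nearest-rank convention
  ranked <- asDiscretized(array(1:10, c(10, 1, 1)), 16)
  hr <- histogramFeatures(ranked)
  expect_equal(unname(hr["hist_p10"]), 1)
  expect_equal(unname(hr["hist_p90"]), 9)
})

test_that("two-voxel and uniform ROIs give the textbook GLCM values", {
  d2 <- asDiscretized(array(c(1L, 2L), c(2, 1, 1)), 2)
  P <- buildGlcm(d2)
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- glcmFeatures(P)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_joint_maximum"]), 0.5)

  du <- asDiscretized(array(1L, c(3, 3, 2)), 4)
  fu <- glcmFeatures(buildGlcm(du))
  expect_equal(unname(fu["glcm_contrast"]), 0)
  expect_equal(unname(fu["glcm_angular_second_moment"]), 1)
  expect_equal(unname(fu["glcm_correlation"]), 1)

  # an isolated voxel has no pairs: NA features with a warning
  iso <- asDiscretized(array(c(1L, NA, NA, NA), c(2, 2, 1)), 2)
  expect_warning(fi <- glcmFeatures(buildGlcm(iso)), "no valid voxel pairs")
  expect_true(all(is.na(fi)))
})

test_that("GLCM is symmetric and all four texture matrices match brute force on random arrays", {
  set.seed(77)
  for (i in 1:12) {
    dims <- c(sample(2:6, 1), sample(2:6, 1), sample(2:4, 1))
    nl <- sample(2:8, 1)
    lab <- randomLabelArray(dims, nl)
    if (sum(!is.na(lab)) < 2) next
    d <- asDiscretized(lab, nl)

    P <- buildGlcm(d)
    expect_identical(P, t(P))
    stripAttr <- function(m) array(as.numeric(m), dim(m))
    expect_equal(P, oracleGlcm(lab, nl), tolerance = 1e-13)
    expect_equal(stripAttr(buildGlrlm(d)), stripAttr(oracleGlrlm(lab, nl)))
    expect_equal(stripAttr(buildGlszm(d)), stripAttr(oracleGlszm(lab, nl)))
    expect_equal(buildNgtdm(d), oracleNgtdm(lab, nl), tolerance = 1e-12)
  }
})

test_that("run and zone summaries match hand-worked examples", {
  # a single 1D run of three equal labels
  run3 <- asDiscretized(array(3L, c(3, 1, 1)), 4)
  R <- buildGlrlm(run3)
  # along the x axis: one run of length 3; the other 12 directions see
  # three runs of length 1 each
  expect_equal(R[3, 3], 1)
  expect_equal(R[3, 1], 36)
  expect_equal(sum(R), 37)

  # all-distinct labels: every run has length 1, run percentage is 1
  dis <- asDiscretized(array(1:4, c(4, 1, 1)), 4)
  expect_equal(unname(glrlmFeatures(buildGlrlm(dis))["glrlm_run_percentage"]), 1)

  # two disjoint single-voxel zones of the same label
  two <- asDiscretized(array(c(1L, 2L, 1L), c(3, 1, 1)), 2)
  Z <- buildGlszm(two)
  expect_equal(Z[1, 1], 2)

  # one connected uniform ROI: a single zone, zone percentage 1/N
  uni <- asDiscretized(array(2L, c(3, 3, 1)), 4)
  fz <- glszmFeatures(buildGlszm(uni))
  expect_equal(unname(fz["glszm_zone_percentage"]), 1 / 9)

  # uniform ROI: all neighbourhood differences zero
  fn <- ngtdmFeatures(buildNgtdm(uni))
  expect_equal(unname(fn["ngtdm_contrast"]), 0)
  # single-voxel ROI: no valid neighbourhood, coarseness capped
  fs <- ngtdmFeatures(buildNgtdm(asDiscretized(array(1L, c(1, 1, 1)), 2)))
  expect_equal(unname(fs["ngtdm_coarseness"]), 1e6)
})

test_that("the feature vector has 73 registry-ordered entries, 62 texture-tagged", {
  st <- makeTestStudy()
  fv <- extractFeatures(scans(st)$SIM, gtv(st))
  expect_length(fv, 73)
  expect_identical(names(fv), featureRegistry()$name)
  expect_identical(sum(attr(fv, "family") != "histogram"), 62L)
  expect_identical(sum(attr(fv, "family") == "histogram"), 11L)
})

test_that("features are invariant under monotone affine intensity transforms", {
  set.seed(13)
  st <- makeTestStudy()
  v <- scans(st)$F1
  fv <- extractFeatures(v, gtv(st), nBins = 32)
  for (ab in list(c(2.7, 5), c(0.01, -3))) {
    v2 <- ImageVolume(ab[1] * voxels(v) + ab[2], spacing(v), "F1", "pt01")
    expect_equal(extractFeatures(v2, gtv(st), nBins = 32), fv,
                 tolerance = 1e-10)
  }
})

test_that("permuting voxels within the mask keeps histogram features, changes texture", {
  set.seed(14)
  st <- makeTestStudy()
  v <- scans(st)$F1
  msk <- voxels(gtv(st))
  vox <- voxels(v)
  vox[msk] <- sample(vox[msk])
  v2 <- ImageVolume(vox, spacing(v), "F1", "pt01")
  f1 <- extractFeatures(v, gtv(st))
  f2 <- extractFeatures(v2, gtv(st))
  histIdx <- attr(f1, "family") == "histogram"
  expect_equal(f2[histIdx], f1[histIdx], tolerance = 1e-12)
  expect_gt(max(abs(f2[!histIdx] - f1[!histIdx]) /
                pmax(abs(f1[!histIdx]), 1e-12)), 0.01)
})

test_that("the shipped registry JSON matches the in-code registry", {
  f <- system.file("extdata", "feature_registry.json",
                   package = "DeltaRadiomics")
  expect_true(nzchar(f))
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(js$name, featureRegistry()$name)
  expect_identical(js$family, featureRegistry()$family)
})
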