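constantKidneyVolume <- function(k = 7, dims = c(6, 6, 9)) {
  vox <- array(1, dims)
  m <- array(FALSE, dims)
  m[2:4, 2:4, 2:8] <- TRUE
  vox[m] <- k
  list(vol = ImageVolume(vox), mask = ROIMask(m, "kidney"))
}

test_that("kidney median pools exactly the three selected slices", {
  ck <- constantKidneyVolume(7)
  expect_identical(kidneyMedian(ck$vol, ck$mask), 7)

  # even-count median convention: mean of the two central order statistics
  vox <- array(0, c(4, 1, 3))
  vox[, 1, 2] <- c(1, 2, 3, 4)
  m <- array(FALSE, c(4, 1, 3)); m[, 1, 2] <- TRUE
  expect_identical(kidneyMedian(ImageVolume(vox), ROIMask(m, "kidney"),
                                slices = c(2L, 2L, 2L)), 2.5)

  # random intensities match a sort-and-pick oracle
  set.seed(8)
  ck2 <- constantKidneyVolume()
  vol <- ImageVolume(array(runif(prod(dim(voxels(ck2$vol)))),
                           dim(voxels(ck2$vol))))
  sl <- selectKidneySlices(ck2$mask)
  keep <- voxels(ck2$mask)
  keep[, , setdiff(1:9, unique(sl))] <- FALSE
  xs <- sort(voxels(vol)[keep])
  n <- length(xs)
  oracle <- if (n %% 2 == 1) xs[(n + 1) / 2] else mean(xs[n / 2 + 0:1])
  expect_identical(kidneyMedian(vol, ck2$mask), oracle)

  # missing kidney on a selected slice is an error
  expect_error(kidneyMedian(ck$vol, ck$mask, slices = c(1L, 5L, 6L)),
               "selected slice")
})

test_that("normalization divides voxels and preserves metadata", {
  v <- ImageVolume(array(6, c(3, 3, 2)), label = "F4", patientId = "pZ")
  nv <- normalizeVolume(v, 2)
  expect_true(all(voxels(nv) == 3))
  expect_identical(scanLabel(nv), "F4")
  expect_identical(patientId(nv), "pZ")
  expect_identical(voxels(normalizeVolume(v, 1)), voxels(v))
  expect_error(normalizeVolume(v, 0), "> 0")
  expect_error(normalizeVolume(v, -2), "> 0")
})

test_that("kidney-median normalization cancels any global rescaling", {
  set.seed(9)
  ck <- constantKidneyVolume()
  dims <- dim(voxels(ck$vol))
  vol <- ImageVolume(array(runif(prod(dims), 1, 5), dims))
  base <- voxels(normalizeVolume(vol, kidneyMedian(vol, ck$mask)))
  for (g in c(0.1, 1, 10)) {
    scaled <- ImageVolume(voxels(vol) * g)
    out <- voxels(normalizeVolume(scaled, kidneyMedian(scaled, ck$mask)))
    expect_lt(max(abs(out - base) / pmax(abs(base), 1e-300)), 1e-12)
  }
  # normalized kidney median is exactly 1
  nv <- normalizeVolume(vol, kidneyMedian(vol, ck$mask))
  expect_equal(kidneyMedian(nv, ck$mask), 1)
})

test_that("drift analysis recovers injected drift and errors on degenerate input", {
  cohort <- generateCohort(syntheticConfig(nPatients = 8,
                                           dims = c(32, 32, 12),
                                           driftSd = 0.25, seed = 21))
  rep <- driftAnalysis(cohort$studies, normalized = FALSE)
  expect_gt(rep$pearsonR, 0.8)
  expect_identical(nrow(rep$perPatient), 8L)
  expect_output(print(rep), "Pearson")

  # after normalization the shared drift is gone
  repN <- driftAnalysis(cohort$studies, normalized = TRUE)
  expect_lt(abs(repN$pearsonR), 0.6)

  expect_error(driftAnalysis(cohort$studies[1:2]), ">= 3")
})
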