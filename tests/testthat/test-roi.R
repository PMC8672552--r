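kidneyMaskOnSlices <- function(slices, nz = 110) {
  m <- array(FALSE, c(4, 4, nz))
  m[2, 2, slices] <- TRUE
  ROIMask(m, "kidney")
}

test_that("kidney slice selection lands at 1/4, 1/2, 3/4 of the slice extent", {
  # extent spanning 35 slices (0-based 62..96 in the motivating example;
  # 1-based here): quarter positions with half-away-from-zero rounding
  expect_identical(selectKidneySlices(kidneyMaskOnSlices(63:97)),
                   c(72L, 80L, 89L))
  # single-slice kidney: the same slice three times
  expect_identical(selectKidneySlices(kidneyMaskOnSlices(7)), c(7L, 7L, 7L))
  # 5-slice extent: brute-force rounding gives offsets 1, 2, 3
  expect_identical(selectKidneySlices(kidneyMaskOnSlices(1:5)), c(2L, 3L, 4L))
  expect_error(selectKidneySlices(
    new("ROIMask", voxels = array(FALSE, c(2, 2, 2)), role = "abdomen",
        patientId = "p")), "empty")
})

test_that("selected kidney slices are non-decreasing and inside the extent", {
  set.seed(5)
  for (i in 1:25) {
    lo <- sample(1:60, 1); hi <- lo + sample(0:40, 1)
    s <- selectKidneySlices(kidneyMaskOnSlices(lo:hi))
    expect_true(all(diff(s) >= 0))
    expect_true(all(s >= lo & s <= hi))
  }
})

test_that("erosion of a 10x10 square at native spacing yields the 8x8 interior", {
  m <- array(FALSE, c(14, 14, 2))
  m[3:12, 3:12, 1] <- TRUE
  er <- perturbRoi(ROIMask(m), mode = "erode")
  expect_identical(sum(voxels(er)), 64L)
  expect_true(all(which(voxels(er)[, , 1], arr.ind = TRUE) >= 4))
  di <- perturbRoi(ROIMask(m), mode = "dilate")
  # dilation with the cross element adds 4 edges of 10 voxels
  expect_identical(sum(voxels(di)), 140L)
})

test_that("identity perturbation returns the mask unchanged", {
  st <- makeTestStudy()
  expect_identical(perturbRoi(gtv(st), mode = "identity"), gtv(st))
})

test_that("erode(m) is a subset of m which is a subset of dilate(m); slice extent fixed", {
  set.seed(6)
  for (i in 1:10) {
    m <- array(FALSE, c(16, 16, 4))
    # shapes kept clear of the grid border so clipping cannot interfere
    cx <- sample(7:9, 1); cy <- sample(7:9, 1); r <- sample(3:4, 1)
    for (k in 1:3)
      m[, , k] <- (row(m[, , k]) - cx)^2 + (col(m[, , k]) - cy)^2 <= r^2
    mk <- ROIMask(m)
    er <- voxels(perturbRoi(mk, mode = "erode"))
    di <- voxels(perturbRoi(mk, mode = "dilate"))
    expect_true(all(!er | m))       # erode subset of m
    expect_true(all(!m | di))       # m subset of dilate
    expect_identical(apply(er, 3, any) | apply(m, 3, any), apply(m, 3, any))
    expect_identical(apply(di, 3, any), apply(m, 3, any))
    # closing property on convex masks: dilate-then-erode recovers m
    cl <- voxels(perturbRoi(perturbRoi(mk, mode = "dilate"), mode = "erode"))
    expect_true(all(!m | cl))
  }
})

test_that("translation mode shifts each slice by one pixel in x and y", {
  m <- array(FALSE, c(12, 12, 2))
  m[3:6, 4:7, 1] <- TRUE
  tr <- perturbRoi(ROIMask(m), mode = "translate")
  expect_identical(voxels(tr)[4:7, 5:8, 1], m[3:6, 4:7, 1])
  expect_identical(sum(voxels(tr)), sum(m))
})

test_that("erosion that wipes out the ROI raises the vanish error", {
  m <- array(FALSE, c(8, 8, 2))
  m[4, 4, 1] <- TRUE
  expect_error(perturbRoi(ROIMask(m), mode = "erode"), "vanished")
})

test_that("abdomen auto-ROI recovers the body on a phantom, minus the GTV", {
  st <- makeTestStudy(dims = c(32, 32, 12))
  v <- scans(st)$SIM
  abd <- abdomenAutoRoi(v, gtv(st))
  expect_identical(roiRole(abd), "abdomen")
  # disjoint from the GTV by construction
  expect_false(any(voxels(abd) & voxels(gtv(st))))
  # restricted to 10 slices around the GTV median slice
  zs <- unique(which(voxels(abd), arr.ind = TRUE)[, 3])
  expect_lte(length(zs), 10)
  # within those slices the mask matches the bright body ellipse closely
  xs <- slice.index(array(0, c(32, 32, 12)), 1)
  ys <- slice.index(array(0, c(32, 32, 12)), 2)
  body <- ((xs - 16)^2 / 14^2 + (ys - 16)^2 / 12^2) <= 1
  expected <- body & !voxels(gtv(st))
  expected[, , setdiff(1:12, zs)] <- FALSE
  agree <- mean(voxels(abd)[, , zs] == expected[, , zs])
  expect_gt(agree, 0.97)
})

test_that("abdomen auto-ROI on a short volume warns and uses all slices", {
  st <- makeTestStudy(dims = c(32, 32, 8))
  expect_warning(abdomenAutoRoi(scans(st)$SIM, gtv(st)), "fewer than 10")
})
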