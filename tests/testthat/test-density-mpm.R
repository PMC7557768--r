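test_that("trackDensityMap counts each streamline once per voxel", {
  g <- smallGrid(c(11L, 5L, 5L))
  # a streamline that re-enters the same voxel twice still counts once
  w <- function(...) voxelToWorld(rbind(...), g)
  s <- w(c(2, 2, 2), c(5, 2, 2), c(2, 2, 2))
  d <- trackDensityMap(tractogram(list(s), g))
  expect_equal(max(values(d)), 1)
  expect_equal(sum(values(d)), 4)  # voxels x = 2..5 on the row
  # two streamlines through one voxel give 2
  d2 <- trackDensityMap(tractogram(list(s, s), g))
  expect_equal(max(values(d2)), 2)
  # empty tractogram gives the zero map
  expect_equal(sum(values(trackDensityMap(tractogram(list(), g)))), 0)
})

test_that("maskDensity multiplies and enforces a shared grid", {
  g <- smallGrid(c(6L, 6L, 6L))
  d <- trackDensityMap(tractogram(list(voxelToWorld(rbind(c(0, 0, 0),
                                                          c(5, 0, 0)), g)),
                                  g))
  mv <- array(0, gridDim(g)); mv[1:2, , ] <- 1
  roi <- binaryMask(g, mv)
  md <- maskDensity(d, roi)
  expect_equal(sum(values(md)), 2)
  g2 <- smallGrid(c(6L, 6L, 6L), vs = 2)
  expect_error(maskDensity(d, binaryMask(g2, array(1, c(6, 6, 6)))))
})

test_that("thresholdRelative keeps values >= fraction of the map maximum", {
  g <- smallGrid(c(4L, 1L, 1L))
  v <- volume(g, array(c(1, 10, 40, 100), c(4, 1, 1)))
  m <- thresholdRelative(v, 0.25)
  expect_equal(as.numeric(values(m)), c(0, 0, 1, 1))
  # boundary value exactly at the threshold is retained (>=)
  v2 <- volume(g, array(c(25, 0, 0, 100), c(4, 1, 1)))
  expect_equal(as.numeric(values(thresholdRelative(v2, 0.25))),
               c(1, 0, 0, 1))
  expect_equal(maskVolume(thresholdRelative(volume(g, 0), 0.25)), 0)
  expect_error(thresholdRelative(v, 0))
  expect_error(thresholdRelative(v, 1))
})

test_that("maximumProbabilityMap thresholds at ceiling(fraction x N)", {
  g <- smallGrid(c(3L, 3L, 1L))
  m1 <- maskFromArray(g, c(1, 1, 1, 0, 0, 0, 0, 0, 0))
  m2 <- maskFromArray(g, c(1, 1, 0, 1, 0, 0, 0, 0, 0))
  m3 <- maskFromArray(g, c(1, 0, 0, 0, 1, 0, 0, 0, 0))
  mpm <- maximumProbabilityMap(list(m1, m2, m3), 0.5)
  # cut = ceiling(1.5) = 2: voxels covered by >= 2 of 3 subjects
  expect_equal(as.numeric(values(mpmMask(mpm)))[1:3], c(1, 1, 0))
  expect_equal(maskVolume(mpmMask(mpm)), 2)
  expect_equal(mpm@nSubjects, 3L)
  expect_error(maximumProbabilityMap(list(m1), 0.5), "at least 2")
})

test_that("percentageOverlap matches Eq. (1) and is asymmetric", {
  g <- smallGrid(c(12L, 1L, 1L))
  A <- maskFromArray(g, c(rep(1, 3), rep(0, 9)))
  B <- maskFromArray(g, rep(1, 12))
  expect_equal(percentageOverlap(A, B), 25)
  expect_equal(percentageOverlap(B, A), 100)
  empty <- maskFromArray(g, rep(0, 12))
  expect_error(percentageOverlap(A, empty), "undefined")
})

test_that("subjectConnectivityCluster composes density, mask, threshold,
           transform in order", {
  g <- smallGrid(c(10L, 10L, 10L))
  w <- function(...) voxelToWorld(rbind(...), g)
  # 3 streamlines through the ROI row, 1 through another ROI row
  sl <- c(rep(list(w(c(0, 4, 4), c(9, 4, 4))), 3),
          list(w(c(0, 5, 4), c(9, 5, 4))))
  tr <- tractogram(sl, g)
  mv <- array(0, gridDim(g)); mv[, 5:6, 5] <- 1
  roi <- binaryMask(g, mv)
  out <- subjectConnectivityCluster(tr, roi, affineTransform(diag(4)), g,
                                    fraction = 0.5)
  # inside the ROI the max is 3 (row y=4); the single-streamline row is
  # below 0.5 x 3 and is dropped
  expect_equal(maskVolume(out), 10)
  idx <- arrayInd(which(values(out) == 1), gridDim(g))
  expect_true(all(idx[, 2] == 5))
})

test_that("tractMpm registers, binarizes then sums subject densities", {
  g <- smallGrid(c(8L, 8L, 8L))
  w <- function(...) voxelToWorld(rbind(...), g)
  d1 <- trackDensityMap(tractogram(list(w(c(0, 3, 3), c(7, 3, 3))), g))
  d2 <- trackDensityMap(tractogram(list(w(c(0, 3, 3), c(7, 3, 3)),
                                        w(c(0, 5, 5), c(7, 5, 5))), g))
  idt <- affineTransform(diag(4))
  mpm <- tractMpm(list(d1, d2), list(idt, idt), g, 0.5)
  # the shared row is covered by both subjects, the extra row by one;
  # cut = ceiling(0.5 x 2) = 1 keeps the union of both rows
  expect_equal(max(values(mpm)), 2)
  expect_equal(maskVolume(mpmMask(mpm)), 16)
  # the retained-by-both core is the shared row only
  expect_equal(sum(values(mpm) == 2), 8)
})
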