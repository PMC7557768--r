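test_that("resolveTrackingParams reproduces the published parameterization", {
  r <- resolveTrackingParams(1.25, trackingParams())
  expect_equal(r$stepMm, 1.5625)
  expect_equal(r$maxAngleDeg, 37.5)
  # the angle is resolution-invariant with the default factors
  expect_equal(resolveTrackingParams(2, trackingParams())$maxAngleDeg, 37.5)
  expect_error(resolveTrackingParams(0))
})

test_that("sampleTrackingDirection respects cutoff, cone and sign", {
  g <- smallGrid(c(5L, 5L, 5L))
  # one voxel with two lobes: +x (amp 1) and +z (amp 0.02, below cutoff)
  vox <- c(63L, 63L)
  f <- orientationField(g, vox, rbind(c(1, 0, 0), c(0, 0, 1)),
                        c(1, 0.02))
  p <- voxelToWorld(matrix(arrayInd(63, gridDim(g)) - 1, 1), g)
  set.seed(5)
  d <- sampleTrackingDirection(f, p, n = 50L)
  # only the supra-cutoff +x lobe can be drawn; without prev the stored
  # orientation is returned (bidirectional launch makes the sign moot)
  expect_true(all(abs(abs(d[, 1]) - 1) < 1e-12))
  # with prev = +x, antipodal resolution forces +x exactly
  d2 <- sampleTrackingDirection(f, p, prev = c(1, 0, 0), n = 20L)
  expect_true(all(d2[, 1] == 1))
  # prev orthogonal to the only admissible lobe: outside the 37.5-degree
  # cone, so every draw signals termination
  d3 <- sampleTrackingDirection(f, p, prev = c(0, 1, 0), n = 10L)
  expect_true(all(is.na(d3)))
  # background amplitude terminates immediately
  fbg <- orientationField(g, 1L, rbind(c(1, 0, 0)), 0.01)
  expect_true(all(is.na(sampleTrackingDirection(fbg, p, n = 5L))))
})

test_that("propagateStreamline on a straight field takes exact chords", {
  g <- smallGrid(c(9L, 30L, 9L))
  f <- straightField(g)
  p0 <- voxelToWorld(matrix(c(4, 15, 4), 1), g)
  set.seed(9)
  s <- propagateStreamline(as.numeric(p0), f,
                           trackingParams(maxLengthMm = 100))
  expect_gt(nrow(s), 10)
  step <- resolveTrackingParams(1, trackingParams())$stepMm
  chords <- sqrt(rowSums(diff(s)^2))
  expect_true(all(abs(chords - step) < 1e-6))
  # straight: x and z constant
  expect_lt(max(abs(s[, 1] - s[1, 1])), 1e-9)
  expect_lt(max(abs(s[, 3] - s[1, 3])), 1e-9)
  # the seed point itself is a vertex of the bidirectional streamline
  expect_true(any(rowSums(abs(sweep(s, 2, as.numeric(p0)))) < 1e-9))
})

test_that("maxLengthMm bounds each half-track arc length", {
  g <- smallGrid(c(9L, 60L, 9L))
  f <- straightField(g)
  p0 <- as.numeric(voxelToWorld(matrix(c(4, 30, 4), 1), g))
  set.seed(10)
  s <- propagateStreamline(p0, f, trackingParams(maxLengthMm = 5))
  # each half <= 5 mm, so the whole streamline spans <= 10 mm
  expect_lte(sum(sqrt(rowSums(diff(s)^2))), 10 + 1e-9)
})

test_that("trackFromSeedMask is deterministic given the RNG seed", {
  g <- smallGrid(c(9L, 30L, 9L))
  f <- straightField(g)
  mv <- array(0, gridDim(g)); mv[4:6, 3:4, 4:6] <- 1
  seed <- binaryMask(g, mv)
  set.seed(123)
  t1 <- trackFromSeedMask(seed, f, trackingParams(seedsPerVoxel = 3))
  set.seed(123)
  t2 <- trackFromSeedMask(seed, f, trackingParams(seedsPerVoxel = 3))
  expect_identical(streamlines(t1), streamlines(t2))
  expect_equal(nStreamlines(t1), 3 * maskVolume(seed))
  # mismatched grids and empty masks are rejected
  g2 <- smallGrid(c(8L, 8L, 8L))
  expect_error(trackFromSeedMask(binaryMask(g2, array(1, c(8, 8, 8))), f))
  expect_error(trackFromSeedMask(binaryMask(g, 0), f), "empty")
})
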