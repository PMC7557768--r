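test_that("imageGrid centres the default affine and validates input", {
  g <- imageGrid(c(4L, 6L, 8L), 2)
  expect_equal(unname(voxelSize(g)), c(2, 2, 2))
  # centre voxel index (dim-1)/2 maps to world origin
  ctr <- voxelToWorld(matrix((c(4, 6, 8) - 1) / 2, 1), g)
  expect_equal(as.numeric(ctr), c(0, 0, 0))
  expect_error(imageGrid(c(0L, 2L, 2L), 1))
  badAff <- diag(4); badAff[4, ] <- c(1, 0, 0, 1)
  expect_error(imageGrid(c(2L, 2L, 2L), 1, badAff))
})

test_that("worldToVoxel uses half-open voxel ownership", {
  g <- imageGrid(c(10L, 10L, 10L), 1)
  ctr <- voxelToWorld(matrix(c(3, 4, 5), 1), g)
  # exactly on the boundary between voxels 2 and 3 along x: belongs to 3
  onEdge <- ctr - c(0.5, 0, 0)
  wv <- worldToVoxel(onEdge, g)
  expect_equal(as.integer(wv$index), c(3L, 4L, 5L))
  justBelow <- ctr - c(0.5 + 1e-9, 0, 0)
  expect_equal(as.integer(worldToVoxel(justBelow, g)$index[1]), 2L)
  # outside flag
  out <- voxelToWorld(matrix(c(-1, 0, 0), 1), g)
  expect_false(worldToVoxel(out, g)$inside)
  expect_error(worldToVoxel(matrix(c(NA, 0, 0), 1), g))
})

test_that("voxelToWorld and worldToVoxel round-trip on random points", {
  set.seed(7)
  g <- imageGrid(c(12L, 9L, 7L), 1.25)
  idx <- cbind(sample(0:11, 50, TRUE), sample(0:8, 50, TRUE),
               sample(0:6, 50, TRUE))
  w <- voxelToWorld(idx, g)
  wv <- worldToVoxel(w, g)
  expect_true(all(wv$inside))
  expect_equal(unname(wv$index), unname(idx))
})

test_that("applyTransform on points matches direct matrix algebra", {
  th <- pi / 7
  M <- diag(4)
  M[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  M[1:3, 4] <- c(1, -2, 0.5)
  tr <- affineTransform(M)
  set.seed(1)
  p <- matrix(rnorm(30), ncol = 3)
  got <- applyTransform(p, tr)
  want <- t(M %*% rbind(t(p), 1))[, 1:3]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("applyTransform on masks is exact for lattice-preserving shifts", {
  g <- imageGrid(c(8L, 8L, 8L), 1)
  set.seed(2)
  m <- binaryMask(g, array(as.double(runif(512) < 0.3), c(8, 8, 8)))
  M <- diag(4); M[1:3, 4] <- c(1, 0, 0)  # shift one voxel in +x (world mm)
  shifted <- applyTransform(m, affineTransform(M), g)
  v <- values(m); sv <- values(shifted)
  expect_equal(sv[2:8, , ], v[1:7, , ])
  # identity transform reproduces the mask exactly
  idt <- applyTransform(m, affineTransform(diag(4)), g)
  expect_identical(values(idt), values(m))
})

test_that("densifyPolyline follows the ceil(len/spacing) contract", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0))
  d <- densifyPolyline(p, 0.5)
  # segment 1: len 1 -> 2 subdivisions; segment 2: len 2 -> 4 subdivisions
  expect_equal(nrow(d), 1 + 2 + 4)
  expect_equal(d[1, ], p[1, ])
  expect_equal(d[nrow(d), ], p[3, ])
  steps <- sqrt(rowSums(diff(d)^2))
  expect_true(all(steps <= 0.5 + 1e-12))
  # single point passes through unchanged
  expect_equal(densifyPolyline(p[1, , drop = FALSE], 0.5),
               p[1, , drop = FALSE])
})

test_that("binarize and maskVolume behave on volumes", {
  g <- imageGrid(c(3L, 3L, 3L), 1)
  v <- volume(g, array(c(rep(0, 20), rep(2.5, 7)), c(3, 3, 3)))
  b <- binarize(v)
  expect_s4_class(b, "BinaryMask")
  expect_equal(maskVolume(b), 7)
})

test_that("Tractogram accessors and validity", {
  g <- imageGrid(c(5L, 5L, 5L), 1)
  sl <- list(matrix(rnorm(9), 3), matrix(rnorm(6), 2))
  tr <- tractogram(sl, g, "toy")
  expect_equal(nStreamlines(tr), 2L)
  expect_identical(streamlines(tr)[[1]], sl[[1]])
  expect_error(tractogram(list(matrix(1, 1, 2)), g))
})
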