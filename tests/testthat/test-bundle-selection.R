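test_that("streamlineIntersects cannot tunnel through a one-voxel slab", {
  g <- smallGrid(c(21L, 5L, 5L))
  mv <- array(0, gridDim(g)); mv[11, , ] <- 1  # one-voxel wall
  wall <- binaryMask(g, mv)
  # a two-point streamline whose vertices straddle the wall
  a <- as.numeric(voxelToWorld(matrix(c(5, 2, 2), 1), g))
  b <- as.numeric(voxelToWorld(matrix(c(15, 2, 2), 1), g))
  expect_true(streamlineIntersects(rbind(a, b), wall))
  # a streamline fully on one side does not touch it
  c2 <- as.numeric(voxelToWorld(matrix(c(8, 2, 2), 1), g))
  expect_false(streamlineIntersects(rbind(a, c2), wall))
})

test_that("selectBundle applies seed, exclude, include in order with tallies", {
  g <- smallGrid(c(21L, 9L, 5L))
  mk <- function(xr) {
    mv <- array(0, gridDim(g)); mv[xr, , ] <- 1; binaryMask(g, mv)
  }
  seed <- mk(1:3); inc <- mk(19:21); exc <- mk(10)
  w <- function(...) {
    idx <- rbind(...)
    voxelToWorld(idx, g)
  }
  sl <- list(
    w(c(1, 4, 2), c(20, 4, 2)),   # seed -> include, crosses exc at x=10
    w(c(1, 4, 2), c(9, 4, 2), c(9, 8, 4), c(20, 8, 4)),  # also hits exc
    w(c(5, 4, 2), c(20, 4, 2)),   # misses the seed
    w(c(2, 4, 2), c(8, 4, 2)),    # seed but never reaches include
    w(c(2, 2, 2), c(2, 8, 2))     # stays inside the seed: fails include
  )
  tr <- tractogram(sl, g, "toy")
  spec <- selectionSpec("toy", seed, include = list(inc),
                        exclude = list(exc))
  res <- selectBundle(tr, spec)
  expect_equal(res@nos, 0L)
  expect_equal(res@rejectedSeed, 1L)
  expect_equal(res@rejectedExclude, 2L)
  expect_equal(res@rejectedInclude, 2L)
  expect_equal(res@nInput, 5L)
  # without the exclusion mask the two through-going streamlines survive
  res2 <- selectBundle(tr, selectionSpec("toy", seed, include = list(inc)))
  expect_equal(res2@nos, 2L)
  # selection is idempotent: re-selecting the kept set keeps everything
  res3 <- selectBundle(res2@tractogram,
                       selectionSpec("toy", seed, include = list(inc)))
  expect_equal(res3@nos, res2@nos)
  expect_equal(res3@nInput, res2@nos)
})

test_that("seedCheck = 'start' requires the first vertex in the seed", {
  g <- smallGrid(c(21L, 5L, 5L))
  mv <- array(0, gridDim(g)); mv[1:3, , ] <- 1
  seed <- binaryMask(g, mv)
  a <- as.numeric(voxelToWorld(matrix(c(10, 2, 2), 1), g))
  b <- as.numeric(voxelToWorld(matrix(c(2, 2, 2), 1), g))
  tr <- tractogram(list(rbind(a, b)), g)  # touches seed but starts outside
  spec <- selectionSpec("s", seed)
  expect_equal(selectBundle(tr, spec, seedCheck = "intersect")@nos, 1L)
  expect_equal(selectBundle(tr, spec, seedCheck = "start")@nos, 0L)
})

test_that("buildPallidotegmentalSpecs builds the six specs of the design", {
  cfg <- phantomConfig()
  s <- generateSubject(cfg, 1, 11L)
  specs <- buildPallidotegmentalSpecs(s@masks)
  expect_named(specs, c("L_GPi_ipsi", "R_GPi_ipsi", "L_GPe_ipsi",
                        "R_GPe_ipsi", "L_GPi_contra", "R_GPi_contra"))
  # ipsilateral: seed GPi, include ipsilateral PPN, exclude GPe + six
  # nuclei + midline slab (8 masks)
  expect_identical(values(specs$L_GPi_ipsi@seed), values(s@masks$GPi_L))
  expect_identical(values(specs$L_GPi_ipsi@include[[1]]),
                   values(s@masks$PPN_L))
  expect_length(specs$L_GPi_ipsi@exclude, 8L)
  expect_length(specs$R_GPe_ipsi@exclude, 8L)
  # contralateral: include the opposite PPN, exclude the six contralateral
  # nuclei and NOT the midline slab
  expect_identical(values(specs$L_GPi_contra@include[[1]]),
                   values(s@masks$PPN_R))
  expect_length(specs$L_GPi_contra@exclude, 6L)
  mid <- values(s@masks$midline)
  for (m in specs$L_GPi_contra@exclude)
    expect_false(identical(values(m), mid))
  # contralateral-nuclei switch widens the ipsilateral exclusion lists
  specs2 <- buildPallidotegmentalSpecs(s@masks, contralateralNuclei = TRUE)
  expect_length(specs2$L_GPi_ipsi@exclude, 14L)
  # missing masks are reported by name
  expect_error(buildPallidotegmentalSpecs(s@masks[-match("PPN_L",
                                                         names(s@masks))]),
               "PPN_L")
})

test_that("selection spec validity rejects overlapping seed and exclude", {
  g <- smallGrid(c(8L, 8L, 8L))
  mv <- array(0, gridDim(g)); mv[1:4, , ] <- 1
  m1 <- binaryMask(g, mv)
  expect_error(selectionSpec("bad", m1, exclude = list(m1)))
})
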