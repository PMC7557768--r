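test_that("phantomConfig geometry is mirror-symmetric and in-grid", {
  cfg <- phantomConfig()
  expect_s4_class(cfg, "PhantomConfig")
  # every left ROI has a right twin mirrored through x = 0
  for (nm in grep("_L$", names(cfg@rois), value = TRUE)) {
    rn <- sub("_L$", "_R", nm)
    expect_true(rn %in% names(cfg@rois))
    expect_equal(cfg@rois[[rn]]$center,
                 cfg@rois[[nm]]$center * c(-1, 1, 1))
    expect_equal(cfg@rois[[rn]]$radiusMm, cfg@rois[[nm]]$radiusMm)
  }
  # planted multipliers follow the effect knobs
  m <- vapply(cfg@bundles, function(b) b@countMultiplier, 0)
  expect_equal(unname(m["L_GPi_ipsi"] / m["L_GPe_ipsi"]), 2.0)
  expect_equal(unname(m["R_GPi_ipsi"] / m["L_GPi_ipsi"]), 1.25)
  expect_equal(unname(m["L_GPi_contra"] / m["L_GPi_ipsi"]), 1.25)
  expect_equal(unname(m["R_GPi_contra"] / m["R_GPi_ipsi"]), 0.875)
})

test_that("partitionTerritories forms an exact tercile partition", {
  g <- smallGrid(c(16L, 16L, 16L))
  cfg <- phantomConfig()
  roi <- rasterizeTemplateMask(list(center = c(0, 0, 0), radiusMm = 5),
                               g)
  terr <- partitionTerritories(roi, c(0, -1, 1))
  expect_named(terr, c("limbic", "associative", "sensorimotor"))
  tot <- Reduce(`+`, lapply(terr, values))
  expect_identical(tot, values(roi))  # disjoint cover of the ROI
  n <- maskVolume(roi)
  sizes <- vapply(terr, maskVolume, 0)
  expect_equal(unname(sizes[1]), ceiling(n / 3))
  expect_equal(unname(sum(sizes)), n)
  expect_true(max(sizes) - min(sizes) <= 1)
  # limbic is the anteroventral tier: lowest projection on (0,-1,1)
  idx <- allVoxIdx <- which(values(roi) == 1)
  proj <- function(m) {
    i <- arrayInd(which(values(m) == 1), gridDim(g)) - 1
    w <- voxelToWorld(i, g)
    w %*% c(0, -1, 1)
  }
  expect_true(max(proj(terr$limbic)) <= min(proj(terr$sensorimotor)))
})

test_that("planted endpoints lie on the ROI surface inside the planted tier", {
  cfg <- phantomConfig()
  for (bn in c("L_GPi_ipsi", "L_GPe_ipsi", "R_GPi_ipsi")) {
    b <- cfg@bundles[[bn]]
    roi <- cfg@rois[[b@seedRoi]]
    ep <- b@controlPoints[1, ]
    expect_equal(sqrt(sum((ep - roi$center)^2)), 0.95 * roi$radiusMm,
                 tolerance = 1e-9)
    # deep in the limbic (anteroventral) tier: negative projection
    expect_lt(sum((ep - roi$center) * c(0, -1, 1)), -0.5 * roi$radiusMm)
  }
})

test_that("generateSubject is reproducible and internally consistent", {
  cfg <- phantomConfig()
  s1 <- generateSubject(cfg, 1, 2024L)
  s2 <- generateSubject(cfg, 1, 2024L)
  expect_identical(s1@trueCounts, s2@trueCounts)
  expect_identical(values(s1@masks$GPi_L), values(s2@masks$GPi_L))
  expect_identical(streamlines(s1@tractograms$L_GPi_ipsi),
                   streamlines(s2@tractograms$L_GPi_ipsi))
  # a different seed gives a different jitter
  s3 <- generateSubject(cfg, 1, 2025L)
  expect_false(identical(s1@transform@matrix, s3@transform@matrix))
  # stored transform is subject -> template: composing with the subject
  # masks recovers the template rasterization
  tpl <- rasterizeTemplateMask(cfg@rois$GPi_L, cfg@grid)
  back <- applyTransform(s1@masks$GPi_L, s1@transform, cfg@grid)
  mism <- sum(abs(values(back) - values(tpl)))
  expect_lt(mism / maskVolume(tpl), 0.5)  # nearest-neighbour edge error only
  # territory sub-masks partition each pallidal mask
  tot <- values(s1@masks$GPi_L_limbic) +
    values(s1@masks$GPi_L_associative) +
    values(s1@masks$GPi_L_sensorimotor)
  expect_true(all(tot <= 1))
})

test_that("ground-truth streamlines start in seed and end in target", {
  cfg <- phantomConfig()
  s <- generateSubject(cfg, 2, 555L)
  for (bn in c("L_GPi_ipsi", "R_GPe_ipsi", "L_GPi_contra")) {
    b <- cfg@bundles[[bn]]
    tr <- s@tractograms[[bn]]
    if (nStreamlines(tr) == 0) next
    starts <- t(vapply(streamlines(tr), function(x) x[1, ], numeric(3)))
    ends <- t(vapply(streamlines(tr), function(x) x[nrow(x), ],
                     numeric(3)))
    inSeed <- ppntract:::pointsInMask(starts, s@masks[[b@seedRoi]])
    inTgt <- ppntract:::pointsInMask(ends, s@masks[[b@targetRoi]])
    expect_gte(mean(inSeed), 0.99)
    expect_gte(mean(inTgt), 0.99)
  }
})

test_that("drawTrueCounts matches the Poisson law of generateSubject", {
  cfg <- phantomConfig()
  set.seed(31)
  tab <- drawTrueCounts(cfg, 400)
  expect_setequal(unique(tab$bundle),
                  c("L_GPi_ipsi", "R_GPi_ipsi", "L_GPe_ipsi", "R_GPe_ipsi",
                    "L_GPi_contra", "R_GPi_contra"))
  mn <- tapply(tab$nos, tab$bundle, mean)
  mu <- vapply(cfg@bundles[names(mn)], expectedCount, 0)
  # Poisson mean mu, n = 400: sd of the mean is sqrt(mu/400) ~ 1
  expect_true(all(abs(mn - mu) < 4 * sqrt(mu / 400)))
})

test_that("the orientation field encodes coverage proportional to multipliers", {
  cfg <- phantomConfig()
  s <- generateSubject(cfg, 3, 99L)
  f <- s@field
  nl <- diff(f@offsets)
  # seed voxels the tracker can use: amplitude above cutoff
  strong <- function(maskName) {
    vox <- which(values(s@masks[[maskName]]) == 1)
    sum(vapply(vox, function(v) {
      if (nl[v] == 0) return(FALSE)
      any(f@amplitudes[(f@offsets[v] + 1):f@offsets[v + 1]] >= 0.025)
    }, TRUE))
  }
  nGPiL <- strong("GPi_L"); nGPeL <- strong("GPe_L")
  nGPiR <- strong("GPi_R"); nGPeR <- strong("GPe_R")
  # GPi holds ipsi (24) + contra (30) + distractor (6) coverage; GPe holds
  # ipsi (12) + distractor (6)
  expect_equal(nGPiL, 60)
  expect_equal(nGPeL, 18)
  expect_equal(nGPiR, 62)  # 30 + 26 + 6
  expect_equal(nGPeR, 21)  # 15 + 6
})

test_that("writeSubject writes a readable on-disk bundle of artifacts", {
  cfg <- phantomConfig()
  s <- generateSubject(cfg, 4, 7L)
  d <- file.path(tempdir(), "subj4")
  writeSubject(s, d)
  expect_true(file.exists(file.path(d, "GPi_L.nii.gz")))
  expect_true(file.exists(file.path(d, "L_GPi_ipsi.tck")))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  m <- readVolumeNifti(file.path(d, "GPi_L.nii.gz"), mask = TRUE)
  expect_equal(values(m), values(s@masks$GPi_L))
  tr <- readTck(file.path(d, "L_GPi_ipsi.tck"), grid = cfg@grid)
  expect_equal(nStreamlines(tr), nStreamlines(s@tractograms$L_GPi_ipsi))
  unlink(d, recursive = TRUE)
})
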