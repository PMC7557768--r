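# Synthetic phantom cohort: template-space geometry emulating bilateral
# pallidal segments (GPi/GPe), the PPN, exclusion nuclei, a midsagittal
# slab, and the six pallidotegmental bundles (GPi-ipsi L/R, GPe-ipsi L/R,
# GPi-contra L/R) plus distractor bundles, with full ground truth: per-
# bundle Poisson streamline counts, per-subject rigid jitter with known
# inverse transforms, and a discrete-lobe orientation field the tracker
# can propagate through.

#' Construct a BundleSpec
#' @param name bundle name.
#' @param controlPoints k x 3 world-mm matrix (k >= 3), seed end first.
#' @param nTrue expected base streamline count.
#' @param dispersionMm per-streamline control-point jitter (mm).
#' @param crossesMidline logical.
#' @param countMultiplier product of effect-size multipliers.
#' @param seedRoi,targetRoi names of the ROIs at the two ends.
#' @return a [BundleSpec-class].
#' @export
bundleSpec <- function(name, controlPoints, nTrue = 200,
                       dispersionMm = 0.5, crossesMidline = FALSE,
                       countMultiplier = 1, seedRoi = "", targetRoi = "") {
  new("BundleSpec", name = name, controlPoints = controlPoints,
      nTrue = nTrue, dispersionMm = dispersionMm,
      crossesMidline = crossesMidline, countMultiplier = countMultiplier,
      seedRoi = seedRoi, targetRoi = targetRoi)
}

# template-space membership predicates -----------------------------------

.sphereMember <- function(points, center, radiusMm) {
  d2 <- (points[, 1] - center[1])^2 + (points[, 2] - center[2])^2 +
    (points[, 3] - center[3])^2
  d2 <= radiusMm^2
}

.slabMember <- function(points, halfWidthMm) {
  points[, 1] >= -halfWidthMm & points[, 1] < halfWidthMm
}

#' Tri-section of a pallidal ROI into functional territories
#'
#' Voxels of the ROI are ranked along the anteroventral-to-posterodorsal
#' axis and split into three equal-count tiers: limbic (most anteroventral),
#' associative (central), sensorimotor (most posterodorsal). This geometric
#' partition stands in for a connectivity-based parcellation; the overlap
#' statistic only requires a disjoint partition of the ROI.
#'
#' @param roiMask a [BinaryMask-class] of the pallidal ROI.
#' @param axis numeric(3): world direction pointing posterodorsal (so the
#'   lowest projections are the most anteroventral voxels).
#' @return named list of three [BinaryMask-class] sub-masks
#'   (\code{limbic}, \code{associative}, \code{sensorimotor}) partitioning
#'   the ROI.
#' @export
partitionTerritories <- function(roiMask, axis = c(0, -1, 1)) {
  g <- roiMask@grid
  idx <- allVoxelIndices(g)
  inRoi <- which(roiMask@values == 1)
  if (length(inRoi) < 3L)
    stop("partitionTerritories: ROI must contain at least 3 voxels")
  w <- voxelToWorld(idx[inRoi, , drop = FALSE], g)
  ax <- axis / sqrt(sum(axis^2))
  proj <- w %*% ax
  ord <- order(proj, inRoi)  # deterministic tie-break by linear index
  n <- length(inRoi)
  k1 <- ceiling(n / 3); k2 <- ceiling(2 * n / 3)
  labs <- integer(n)
  labs[ord[seq_len(k1)]] <- 1L                    # limbic (anteroventral)
  labs[ord[(k1 + 1):k2]] <- 2L                    # associative (central)
  labs[ord[(k2 + 1):n]] <- 3L                     # sensorimotor
  out <- list()
  for (i in 1:3) {
    v <- array(0, g@dim)
    v[inRoi[labs == i]] <- 1
    out[[c("limbic", "associative", "sensorimotor")[i]]] <- binaryMask(g, v)
  }
  out
}

#' Construct a PhantomConfig
#'
#' Builds the default template geometry on a 40 x 48 x 32 grid of 1.25 mm
#' isotropic voxels (world origin at the grid centre; x = left-right with
#' the midsagittal plane at x = 0, y = posterior-anterior, z =
#' inferior-superior). Spherical ROIs: GPi (r = 3.125 mm) and GPe
#' (r = 3.75 mm) per hemisphere, PPN (r = 2.5 mm) near the midline
#' inferiorly, and six exclusion nuclei per hemisphere (caudate, putamen,
#' accumbens, STN, SNc, SNr; r = 1.875 mm); a 2-voxel midsagittal slab.
#' Six pallidotegmental bundles curve from the pallidal segments through a
#' peduncle-like waypoint down to the PPN; contralateral GPi bundles cross
#' the midline low, near the tegmental decussation. GPi/GPe bundles
#' terminate on the ROI surface at the pole of the planted territory
#' (default limbic, the anteroventral tier), tilted ventrally so the
#' course exits the ROI tangentially. Expected streamline counts are
#' \code{nTrueBase x multiplier} with multipliers 1 (L GPe),
#' rl (R GPe), gg (L GPi), gg x rl (R GPi), gg x contraLeft (L contra),
#' gg x rl x contraRight (R contra); in the orientation field each
#' bundle's terminal field inside its seed ROI covers a number of voxels
#' proportional to the multiplier (see [generateOrientationField()]), so
#' stronger tracts expose proportionally more seed voxels to the tracker
#' and tracked counts recover the planted ordering.
#'
#' @param dims grid dimensions (default \code{c(40, 48, 32)}).
#' @param voxelSizeMm voxel edge (default 1.25).
#' @param nTrueBase base expected count (default 200).
#' @param dispersionMm streamline jitter (default 0.5 mm).
#' @param gpiOverGpeRatio GPi/GPe expected-count ratio (default 2).
#' @param rightOverLeftRatio right/left ratio (default 1.25).
#' @param contraLeftFactor,contraRightFactor contralateral-over-ipsilateral
#'   factors for the left (default 1.25) and right (default 0.875) GPi.
#' @param maxTranslationMm,maxRotationDeg rigid jitter bounds (default 2 mm,
#'   2 degrees).
#' @param masterSeed master seed (default 42).
#' @param plantedTerritory territory the pallidal bundle endpoints are
#'   planted in (default "limbic").
#' @param slabThicknessVox midline slab thickness in voxels (default 2).
#' @param nTrueDistractor expected count of each distractor bundle
#'   (default 50).
#' @return a [PhantomConfig-class].
#' @export
phantomConfig <- function(dims = c(40L, 48L, 32L), voxelSizeMm = 1.25,
                          nTrueBase = 200, dispersionMm = 0.5,
                          gpiOverGpeRatio = 2.0, rightOverLeftRatio = 1.25,
                          contraLeftFactor = 1.25, contraRightFactor = 0.875,
                          maxTranslationMm = 2, maxRotationDeg = 2,
                          masterSeed = 42L, plantedTerritory = "limbic",
                          slabThicknessVox = 2L, nTrueDistractor = 50) {
  grid <- imageGrid(as.integer(dims), voxelSizeMm)
  vi2w <- function(i) {
    m <- matrix(as.numeric(i), ncol = 3, byrow = TRUE)
    sweep(m, 2, (dims - 1) / 2) * voxelSizeMm
  }
  mirror <- function(w) { w[, 1] <- -w[, 1]; w }
  rv <- function(r) r * voxelSizeMm

  roisL <- list(
    GPe_L       = list(center = vi2w(c(8, 30, 20))[1, ],  radiusMm = rv(3)),
    GPi_L       = list(center = vi2w(c(14, 30, 20))[1, ], radiusMm = rv(2.5)),
    PPN_L       = list(center = vi2w(c(16, 14, 8))[1, ],  radiusMm = rv(2)),
    caudate_L   = list(center = vi2w(c(10, 40, 24))[1, ], radiusMm = rv(1.5)),
    putamen_L   = list(center = vi2w(c(5, 36, 24))[1, ],  radiusMm = rv(1.5)),
    accumbens_L = list(center = vi2w(c(9, 42, 16))[1, ],  radiusMm = rv(1.5)),
    STN_L       = list(center = vi2w(c(9, 24, 18))[1, ],  radiusMm = rv(1.5)),
    SNc_L       = list(center = vi2w(c(10, 18, 10))[1, ], radiusMm = rv(1.5)),
    SNr_L       = list(center = vi2w(c(8, 20, 9))[1, ],   radiusMm = rv(1.5)))
  roisR <- lapply(roisL, function(r)
    list(center = c(-r$center[1], r$center[2:3]), radiusMm = r$radiusMm))
  names(roisR) <- sub("_L$", "_R", names(roisL))
  rois <- c(roisL, roisR)
  rois$midline <- list(slab = TRUE, thicknessVox = as.integer(slabThicknessVox),
                       halfWidthMm = slabThicknessVox * voxelSizeMm / 2)

  # planted endpoints: on the ROI surface at the planted-territory pole,
  # tilted ventrally so the descending course exits the ROI tangentially
  # instead of re-entering it
  terrAxis <- c(0, -1, 1)
  terrDir <- switch(plantedTerritory,
                    limbic = c(0, 1, -1) / sqrt(2),
                    associative = c(0, -1, -1) / sqrt(2),
                    sensorimotor = c(0, -1, 1) / sqrt(2))
  endpoint <- function(roiName) {
    u <- terrDir + c(0, 0, -0.6)
    u <- u / sqrt(sum(u^2))
    rois[[roiName]]$center + 0.95 * rois[[roiName]]$radiusMm * u
  }
  epGPiL <- endpoint("GPi_L"); epGPeL <- endpoint("GPe_L")
  epGPiR <- endpoint("GPi_R"); epGPeR <- endpoint("GPe_R")

  gg <- gpiOverGpeRatio; rl <- rightOverLeftRatio
  mk <- function(name, cp, mult, cross, seedRoi, targetRoi,
                 nTrue = nTrueBase)
    bundleSpec(name, cp, nTrue = nTrue, dispersionMm = dispersionMm,
               crossesMidline = cross, countMultiplier = mult,
               seedRoi = seedRoi, targetRoi = targetRoi)

  cpGPiIpsiL <- rbind(epGPiL,
                      vi2w(c(14.5, 28.5, 16, 15, 24, 14, 15, 20, 12,
                             16, 14, 8)))
  cpGPeIpsiL <- rbind(epGPeL,
                      vi2w(c(10.5, 28.5, 16.5, 13, 25, 15, 15, 20, 12,
                             16, 14, 8)))
  cpGPiContraL <- rbind(epGPiL,
                        vi2w(c(17, 29, 17, 20, 24, 14, 22, 18, 10,
                               23, 14, 8)))
  cpDistGPiL <- vi2w(c(14, 28, 22, 11.5, 26, 20, 9, 24, 18))
  cpDistGPeL <- vi2w(c(8, 28, 22, 6.5, 33, 22, 5, 36, 24))

  bundles <- list(
    L_GPi_ipsi = mk("L_GPi_ipsi", cpGPiIpsiL, gg, FALSE, "GPi_L", "PPN_L"),
    R_GPi_ipsi = mk("R_GPi_ipsi", mirror(cpGPiIpsiL), gg * rl, FALSE,
                    "GPi_R", "PPN_R"),
    L_GPe_ipsi = mk("L_GPe_ipsi", cpGPeIpsiL, 1, FALSE, "GPe_L", "PPN_L"),
    R_GPe_ipsi = mk("R_GPe_ipsi", mirror(cpGPeIpsiL), rl, FALSE,
                    "GPe_R", "PPN_R"),
    L_GPi_contra = mk("L_GPi_contra", cpGPiContraL, gg * contraLeftFactor,
                      TRUE, "GPi_L", "PPN_R"),
    R_GPi_contra = mk("R_GPi_contra", mirror(cpGPiContraL),
                      gg * rl * contraRightFactor, TRUE, "GPi_R", "PPN_L"),
    L_GPi_distractor = mk("L_GPi_distractor", cpDistGPiL, 0.5, FALSE,
                          "GPi_L", "STN_L", nTrue = 2 * nTrueDistractor),
    R_GPi_distractor = mk("R_GPi_distractor", mirror(cpDistGPiL), 0.5, FALSE,
                          "GPi_R", "STN_R", nTrue = 2 * nTrueDistractor),
    L_GPe_distractor = mk("L_GPe_distractor", cpDistGPeL, 0.5, FALSE,
                          "GPe_L", "putamen_L", nTrue = 2 * nTrueDistractor),
    R_GPe_distractor = mk("R_GPe_distractor", mirror(cpDistGPeL), 0.5, FALSE,
                          "GPe_R", "putamen_R", nTrue = 2 * nTrueDistractor))

  new("PhantomConfig", grid = grid, rois = rois, bundles = bundles,
      territoryAxis = terrAxis, gpiOverGpeRatio = gpiOverGpeRatio,
      rightOverLeftRatio = rightOverLeftRatio,
      contraLeftFactor = contraLeftFactor,
      contraRightFactor = contraRightFactor,
      maxTranslationMm = maxTranslationMm, maxRotationDeg = maxRotationDeg,
      masterSeed = as.integer(masterSeed),
      plantedTerritory = plantedTerritory)
}

#' Rasterize a template ROI definition onto a grid
#'
#' @param roi a list with \code{center}/\code{radiusMm} (sphere) or
#'   \code{slab = TRUE} with \code{halfWidthMm}.
#' @param grid target [ImageGrid-class].
#' @param transform optional [AffineTransform-class] mapping template world
#'   to the grid's world space (identity by default): membership of each
#'   voxel centre is evaluated at its back-transformed template position.
#' @return a [BinaryMask-class].
#' @export
rasterizeTemplateMask <- function(roi, grid, transform = NULL) {
  ctr <- voxelToWorld(allVoxelIndices(grid), grid)
  if (!is.null(transform)) {
    inv <- solve(transform@matrix)
    ctr <- cbind(ctr, 1) %*% t(inv)
    ctr <- ctr[, 1:3, drop = FALSE]
  }
  member <- if (isTRUE(roi$slab)) .slabMember(ctr, roi$halfWidthMm)
            else .sphereMember(ctr, roi$center, roi$radiusMm)
  binaryMask(grid, array(as.double(member), grid@dim))
}

# rigid jitter: rotation about the world origin (grid centre) + translation
.drawJitter <- function(maxTransMm, maxRotDeg) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -maxRotDeg, maxRotDeg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t <- runif(3, -maxTransMm, maxTransMm)
  m <- diag(4); m[1:3, 1:3] <- R; m[1:3, 4] <- t
  m
}

# smooth centreline through (jittered) control points: cubic spline per
# coordinate over the chord-length parameter, sampled at ~spacing mm
.smoothCurve <- function(cp, spacingMm = 1) {
  d <- sqrt(rowSums(diff(cp)^2))
  t <- c(0, cumsum(d))
  n <- max(8L, ceiling(t[length(t)] / spacingMm))
  tt <- seq(0, t[length(t)], length.out = n + 1L)
  cbind(stats::spline(t, cp[, 1], xout = tt)$y,
        stats::spline(t, cp[, 2], xout = tt)$y,
        stats::spline(t, cp[, 3], xout = tt)$y)
}

#' Generate the orientation field for one subject
#'
#' Outside the pallidal seed ROIs, every voxel whose centre lies within
#' \code{tubeRadiusVox} voxels of a bundle's centreline receives one lobe
#' per covering bundle; the lobe points from the voxel centre toward a
#' centreline sample \code{lookAheadVox} voxels further along the course
#' (toward the PPN end), so off-axis trajectories converge onto the tract
#' like fibres funnelling into a terminal field, with amplitude drawn
#' uniformly in [0.3, 1]. Inside each pallidal seed ROI, the bundle's
#' terminal arborization is modelled as a coverage set of
#' \code{round(coverageVoxelsBase x countMultiplier)} ROI voxels nearest
#' the bundle's planted endpoint, assigned disjointly across the bundles
#' seeded in that ROI (in list order); only coverage voxels carry lobes
#' there, so the number of seed voxels exposed to the tracker scales with
#' the bundle's expected-count multiplier. Background voxels hold a single
#' isotropic lobe of amplitude 0.01, below the tracking cutoff of 0.025,
#' so propagation terminates there.
#'
#' @param rois named list of [BinaryMask-class]; entries named
#'   \code{GPi_L/R}, \code{GPe_L/R} are treated as pallidal seed ROIs for
#'   the coverage rule.
#' @param bundles named list of [BundleSpec-class] with control points in
#'   the target world space (seed end first).
#' @param grid the [ImageGrid-class].
#' @param tubeRadiusVox tube radius in voxels (default 2).
#' @param lookAheadVox funnel look-ahead distance in voxels (default 6).
#' @param backgroundAmplitude amplitude of background lobes (default 0.01).
#' @param coverageVoxelsBase seed-ROI coverage voxels per unit count
#'   multiplier (default 12).
#' @return an [OrientationField-class].
#' @export
generateOrientationField <- function(rois, bundles, grid,
                                     tubeRadiusVox = 2, lookAheadVox = 6,
                                     backgroundAmplitude = 0.01,
                                     coverageVoxelsBase = 12) {
  vs <- mean(voxelSize(grid))
  nv <- prod(grid@dim)
  ctr <- voxelToWorld(allVoxelIndices(grid), grid)
  pallidal <- intersect(c("GPi_L", "GPi_R", "GPe_L", "GPe_R"), names(rois))
  pallLin <- integer(0)
  roiLin <- list()
  for (nm in pallidal) {
    roiLin[[nm]] <- which(rois[[nm]]@values == 1)
    pallLin <- c(pallLin, roiLin[[nm]])
  }
  taken <- lapply(roiLin, function(x) logical(length(x)))
  lobes <- vector("list", length(bundles))
  names(lobes) <- names(bundles)
  for (bi in seq_along(bundles)) {
    b <- bundles[[bi]]
    cl <- .smoothCurve(b@controlPoints, spacingMm = vs / 2)
    ns <- nrow(cl)
    maxR <- tubeRadiusVox * vs
    # restrict to the bounding box of the tube
    lo <- apply(cl, 2, min) - maxR - vs
    hi <- apply(cl, 2, max) + maxR + vs
    inBox <- which(ctr[, 1] >= lo[1] & ctr[, 1] <= hi[1] &
                   ctr[, 2] >= lo[2] & ctr[, 2] <= hi[2] &
                   ctr[, 3] >= lo[3] & ctr[, 3] <= hi[3])
    if (length(inBox) == 0L) next
    sub <- ctr[inBox, , drop = FALSE]
    best <- rep(Inf, length(inBox))
    bestI <- integer(length(inBox))
    for (s in seq_len(ns)) {
      d2 <- (sub[, 1] - cl[s, 1])^2 + (sub[, 2] - cl[s, 2])^2 +
        (sub[, 3] - cl[s, 3])^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      bestI[upd] <- s
    }
    inTube <- sqrt(best) <= maxR
    vox <- inBox[inTube]
    ni <- bestI[inTube]
    # inside pallidal seed ROIs the tube rule is replaced by coverage
    drop <- vox %in% pallLin
    vox <- vox[!drop]; ni <- ni[!drop]
    if (b@seedRoi %in% pallidal) {
      rl <- roiLin[[b@seedRoi]]
      free <- which(!taken[[b@seedRoi]])
      nCov <- min(length(free),
                  max(1L, round(coverageVoxelsBase * b@countMultiplier)))
      ep <- b@controlPoints[1, ]
      d2 <- (ctr[rl[free], 1] - ep[1])^2 + (ctr[rl[free], 2] - ep[2])^2 +
        (ctr[rl[free], 3] - ep[3])^2
      pick <- free[order(d2, rl[free])[seq_len(nCov)]]
      taken[[b@seedRoi]][pick] <- TRUE
      covVox <- rl[pick]
      # nearest centreline sample for each coverage voxel
      covNi <- integer(length(covVox))
      bestC <- rep(Inf, length(covVox))
      cc <- ctr[covVox, , drop = FALSE]
      for (s in seq_len(ns)) {
        d2 <- (cc[, 1] - cl[s, 1])^2 + (cc[, 2] - cl[s, 2])^2 +
          (cc[, 3] - cl[s, 3])^2
        upd <- d2 < bestC
        bestC[upd] <- d2[upd]
        covNi[upd] <- s
      }
      vox <- c(vox, covVox)
      ni <- c(ni, covNi)
    }
    if (length(vox) == 0L) next
    look <- max(1L, round(lookAheadVox * vs / (vs / 2)))
    tgtI <- pmin(ni + look, ns)
    dir <- cl[tgtI, , drop = FALSE] - ctr[vox, , drop = FALSE]
    # at the PPN end fall back to the local tangent
    atEnd <- tgtI == ni
    if (any(atEnd)) {
      tan <- cl[pmin(ni[atEnd] + 1L, ns), , drop = FALSE] -
        cl[pmax(ni[atEnd] - 1L, 1L), , drop = FALSE]
      dir[atEnd, ] <- tan
    }
    nrm <- sqrt(rowSums(dir^2))
    ok <- nrm > 1e-12
    vox <- vox[ok]; dir <- dir[ok, , drop = FALSE] / nrm[ok]
    amp <- runif(length(vox), 0.3, 1.0)
    lobes[[bi]] <- list(vox = vox, dir = dir, amp = amp)
  }
  vox <- unlist(lapply(lobes, function(l) l$vox))
  dir <- do.call(rbind, lapply(lobes, function(l) l$dir))
  amp <- unlist(lapply(lobes, function(l) l$amp))
  bg <- setdiff(seq_len(nv), unique(vox))
  vox <- c(vox, bg)
  dir <- rbind(dir, matrix(rep(c(1, 0, 0), length(bg)), ncol = 3,
                           byrow = TRUE))
  amp <- c(amp, rep(backgroundAmplitude, length(bg)))
  ord <- order(vox)
  vox <- vox[ord]; dir <- dir[ord, , drop = FALSE]; amp <- amp[ord]
  counts <- tabulate(vox, nbins = nv)
  offsets <- c(0L, cumsum(counts))
  new("OrientationField", grid = grid, offsets = as.integer(offsets),
      directions = dir, amplitudes = amp)
}

#' Construct an OrientationField from explicit per-voxel lobes
#'
#' @param grid an [ImageGrid-class].
#' @param voxels integer vector of 1-based linear voxel indices
#'   (column-major, x fastest), one entry per lobe.
#' @param directions L x 3 matrix of directions (normalized internally).
#' @param amplitudes numeric vector of lobe amplitudes.
#' @return an [OrientationField-class].
#' @export
orientationField <- function(grid, voxels, directions, amplitudes) {
  nv <- prod(grid@dim)
  nrm <- sqrt(rowSums(directions^2))
  directions <- directions / nrm
  ord <- order(voxels)
  counts <- tabulate(voxels, nbins = nv)
  new("OrientationField", grid = grid,
      offsets = as.integer(c(0L, cumsum(counts))),
      directions = directions[ord, , drop = FALSE],
      amplitudes = amplitudes[ord])
}

#' Expected streamline count of a bundle
#' @param b a [BundleSpec-class].
#' @return \code{nTrue x countMultiplier}.
#' @export
expectedCount <- function(b) b@nTrue * b@countMultiplier

#' Draw ground-truth per-bundle streamline counts for a cohort
#'
#' Fast path used for calibration studies: per-subject realized counts are
#' Poisson with mean \code{nTrue x countMultiplier}, the same law
#' [generateSubject()] uses, without building images or streamlines.
#'
#' @param config a [PhantomConfig-class].
#' @param nSubjects number of subjects.
#' @param bundles names of bundles to draw (default: the six
#'   pallidotegmental bundles).
#' @return data.frame with columns subject, bundle, nos.
#' @export
drawTrueCounts <- function(config, nSubjects,
                           bundles = c("L_GPi_ipsi", "R_GPi_ipsi",
                                       "L_GPe_ipsi", "R_GPe_ipsi",
                                       "L_GPi_contra", "R_GPi_contra")) {
  out <- expand.grid(subject = sprintf("sub-%03d", seq_len(nSubjects)),
                     bundle = bundles, stringsAsFactors = FALSE)
  mu <- vapply(config@bundles[out$bundle], expectedCount, 0)
  out$nos <- rpois(nrow(out), mu)
  out[order(out$subject, out$bundle), c("subject", "bundle", "nos")]
}

#' Generate one synthetic subject
#'
#' Draws a rigid jitter (translation and rotation within the configured
#' bounds) mapping template to subject space and stores its inverse as the
#' subject-to-template transform; rasterizes all ROI masks, the midline
#' slab and the territory sub-masks in subject space; realizes per-bundle
#' streamline counts as Poisson(nTrue x multiplier) and builds each
#' ground-truth streamline as a smooth curve through independently jittered
#' control points (resampled until the pallidal end lands in the seed ROI
#' and the far end in the target ROI); and builds the subject's orientation
#' field. Fully reproducible from \code{seed}.
#'
#' @param config a [PhantomConfig-class].
#' @param subjectId integer subject number.
#' @param seed integer RNG seed for this subject.
#' @return a [SyntheticSubject-class].
#' @export
generateSubject <- function(config, subjectId, seed) {
  set.seed(seed)
  grid <- config@grid
  jit <- .drawJitter(config@maxTranslationMm, config@maxRotationDeg)
  jitT <- affineTransform(jit)           # template -> subject (world)
  subj2tpl <- affineTransform(solve(jit))

  # subject-space masks: evaluate template membership at back-transformed
  # voxel centres (exact nearest-neighbour rasterization of the analytic
  # shapes)
  masks <- list()
  for (nm in names(config@rois))
    masks[[nm]] <- rasterizeTemplateMask(config@rois[[nm]], grid, jitT)

  # guard: jitter must not push any ROI off the lattice
  for (nm in names(config@rois)) {
    r <- config@rois[[nm]]
    if (isTRUE(r$slab)) next
    cs <- (jit %*% c(r$center, 1))[1:3]
    cv <- (solve(grid@affine) %*% c(cs, 1))[1:3]
    rvx <- r$radiusMm / voxelSize(grid)
    if (any(cv - rvx < -0.5) || any(cv + rvx > grid@dim - 0.5))
      stop("generateSubject: ROI '", nm, "' leaves the grid after jitter; ",
           "reduce maxTranslationMm/maxRotationDeg")
  }

  # territory sub-masks: label in template space, carry to subject space
  for (seg in c("GPi_L", "GPi_R", "GPe_L", "GPe_R")) {
    tplMask <- rasterizeTemplateMask(config@rois[[seg]], grid)
    terr <- partitionTerritories(tplMask, config@territoryAxis)
    for (tn in names(terr))
      masks[[paste(seg, tn, sep = "_")]] <-
        applyTransform(terr[[tn]], jitT, grid)
  }

  # bundles in subject space
  subjBundles <- config@bundles
  for (bn in names(subjBundles)) {
    b <- subjBundles[[bn]]
    b@controlPoints <- applyTransform(b@controlPoints, jitT)
    subjBundles[[bn]] <- b
  }

  # ground-truth tractograms
  tracts <- list()
  trueCounts <- numeric(0)
  for (bn in names(subjBundles)) {
    b <- subjBundles[[bn]]
    cnt <- rpois(1, expectedCount(b))
    trueCounts[bn] <- cnt
    seedMask <- masks[[b@seedRoi]]
    targetMask <- masks[[b@targetRoi]]
    sl <- vector("list", cnt)
    for (i in seq_len(cnt)) {
      for (try in 1:20) {
        cp <- b@controlPoints +
          matrix(rnorm(length(b@controlPoints), 0, b@dispersionMm),
                 ncol = 3)
        startOk <- pointsInMask(cp[1, , drop = FALSE], seedMask)
        endOk <- pointsInMask(cp[nrow(cp), , drop = FALSE], targetMask)
        if (startOk && endOk) break
        if (try == 20L) cp <- b@controlPoints  # fall back to the centreline
      }
      sl[[i]] <- .smoothCurve(cp, spacingMm = mean(voxelSize(grid)) / 2)
    }
    tracts[[bn]] <- new("Tractogram", streamlines = sl, grid = grid,
                        name = bn)
  }

  field <- generateOrientationField(masks, subjBundles, grid)

  new("SyntheticSubject", id = sprintf("sub-%03d", subjectId),
      masks = masks, field = field, tractograms = tracts,
      transform = subj2tpl, trueCounts = trueCounts, grid = grid)
}

#' Generate a phantom cohort
#'
#' Subject seeds are derived deterministically from the master seed; the
#' effect-size multipliers are identical across subjects.
#'
#' @param config a [PhantomConfig-class].
#' @param nSubjects number of subjects (>= 2).
#' @return list of [SyntheticSubject-class].
#' @export
generateCohort <- function(config, nSubjects) {
  if (nSubjects < 2L) stop("generateCohort: nSubjects must be >= 2")
  set.seed(config@masterSeed)
  seeds <- sample.int(.Machine$integer.max - 1L, nSubjects)
  lapply(seq_len(nSubjects), function(i)
    generateSubject(config, i, seeds[i]))
}

setMethod("show", "SyntheticSubject", function(object) {
  cat("SyntheticSubject", object@id, "|", length(object@masks), "masks |",
      length(object@tractograms), "ground-truth bundles\n")
})

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig:", paste(object@grid@dim, collapse = " x "),
      "grid |", length(object@rois), "ROIs |", length(object@bundles),
      "bundles | GPi/GPe =", object@gpiOverGpeRatio,
      "| R/L =", object@rightOverLeftRatio, "\n")
})

#' Write a synthetic subject to disk
#'
#' Masks as NIfTI-1, ground-truth bundles as TCK, the orientation field as
#' a 4-D NIfTI of (dx, dy, dz, amplitude) quadruples per lobe slot, and a
#' CSV manifest of true counts plus the subject-to-template transform.
#'
#' @param subject a [SyntheticSubject-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSubject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(subject@masks))
    writeVolumeNifti(subject@masks[[nm]],
                     file.path(dir, paste0(nm, ".nii.gz")))
  for (bn in names(subject@tractograms))
    writeTck(subject@tractograms[[bn]],
             file.path(dir, paste0(bn, ".tck")))
  f <- subject@field
  nv <- prod(f@grid@dim)
  nl <- diff(f@offsets)
  M <- max(nl)
  arr <- array(0, c(f@grid@dim, 4L * M))
  for (v in which(nl > 0)) {
    rows <- (f@offsets[v] + 1L):f@offsets[v + 1L]
    ijk <- arrayInd(v, f@grid@dim)
    for (k in seq_along(rows)) {
      arr[ijk[1], ijk[2], ijk[3], (k - 1L) * 4L + 1:3] <-
        f@directions[rows[k], ]
      arr[ijk[1], ijk[2], ijk[3], (k - 1L) * 4L + 4L] <-
        f@amplitudes[rows[k]]
    }
  }
  im <- RNifti::asNifti(arr)
  RNifti::writeNifti(im, file.path(dir, "orientation_field.nii.gz"))
  manifest <- data.frame(bundle = names(subject@trueCounts),
                         true_count = as.integer(subject@trueCounts))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(as.data.frame(subject@transform@matrix),
            file.path(dir, "subject_to_template.csv"), row.names = FALSE)
  invisible(dir)
}
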