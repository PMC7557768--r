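# Probabilistic tractography over discrete-lobe orientation fields.
# The parameterization mirrors common FOD-based probabilistic tracking:
# step = 1.25 x voxel size, maximum turning angle = 30 degrees x
# step / voxel size (37.5 degrees for any isotropic voxel), amplitude
# cutoff 0.025, with bidirectional launching from each seed.

#' Construct TrackingParams
#'
#' @param seedsPerVoxel seeds per seed-mask voxel (default 10; scale up to
#'   1000 for full-effort runs).
#' @param stepFactor step size as a multiple of voxel size (default 1.25).
#' @param angleFactorDeg angle factor (default 30): max turning angle per
#'   step is \code{angleFactorDeg x stepFactor} degrees.
#' @param cutoff minimum lobe amplitude to continue (default 0.025).
#' @param maxLengthMm maximum half-track arc length (default 100 mm).
#' @param minPoints minimum points per kept streamline (default 2).
#' @param maxTrials rejection-sampling budget per step (default 1000).
#' @return a [TrackingParams-class].
#' @export
trackingParams <- function(seedsPerVoxel = 10L, stepFactor = 1.25,
                           angleFactorDeg = 30, cutoff = 0.025,
                           maxLengthMm = 100, minPoints = 2L,
                           maxTrials = 1000L) {
  new("TrackingParams", seedsPerVoxel = as.integer(seedsPerVoxel),
      stepFactor = stepFactor, angleFactorDeg = angleFactorDeg,
      cutoff = cutoff, maxLengthMm = maxLengthMm,
      minPoints = as.integer(minPoints), maxTrials = as.integer(maxTrials))
}

setMethod("show", "TrackingParams", function(object) {
  cat("TrackingParams:", object@seedsPerVoxel, "seeds/voxel | step =",
      object@stepFactor, "x voxel | angle =", object@angleFactorDeg,
      "x step/voxel deg | cutoff =", object@cutoff, "\n")
})

#' Resolve step size and maximum angle for a voxel size
#'
#' step = stepFactor x voxel size (mm); max angle = angleFactorDeg x
#' step / voxel size (degrees). With the default factors the angle is
#' 37.5 degrees regardless of resolution.
#'
#' @param voxelSizeMm scalar voxel size (mm).
#' @param params a [TrackingParams-class].
#' @return list with \code{stepMm} and \code{maxAngleDeg}.
#' @examples
#' resolveTrackingParams(1.25, trackingParams())
#' # $stepMm 1.5625, $maxAngleDeg 37.5
#' @export
resolveTrackingParams <- function(voxelSizeMm, params = trackingParams()) {
  if (voxelSizeMm <= 0) stop("voxel size must be > 0")
  stepMm <- params@stepFactor * voxelSizeMm
  list(stepMm = stepMm,
       maxAngleDeg = params@angleFactorDeg * stepMm / voxelSizeMm)
}

.fieldArgs <- function(field) {
  list(dims = field@grid@dim,
       invAffine = solve(field@grid@affine),
       offsets = field@offsets,
       dirs = field@directions,
       amps = field@amplitudes)
}

#' Sample tracking directions at a point
#'
#' Draws directions with probability proportional to lobe amplitude among
#' lobes at or above the cutoff, restricted (when \code{prev} is given) to
#' the cone of half-angle \code{maxAngleDeg} around \code{prev} with
#' antipodal sign resolved toward \code{prev}; rejection sampling with at
#' most \code{maxTrials} draws. Rows of NA signal termination (no
#' admissible lobe or trials exhausted).
#'
#' @param field an [OrientationField-class].
#' @param point world-mm coordinate (length 3) inside the grid.
#' @param prev previous unit direction, or NULL at seeding.
#' @param maxAngleDeg cone half-angle in degrees.
#' @param cutoff minimum lobe amplitude.
#' @param n number of independent draws (default 1).
#' @param maxTrials rejection budget per draw.
#' @return n x 3 matrix of unit directions (NA rows = termination signal).
#' @export
sampleTrackingDirection <- function(field, point, prev = NULL,
                                    maxAngleDeg = 37.5, cutoff = 0.025,
                                    n = 1L, maxTrials = 1000L) {
  fa <- .fieldArgs(field)
  .cppSampleDirections(fa$dims, fa$invAffine, fa$offsets, fa$dirs, fa$amps,
                       as.numeric(point), prev, maxAngleDeg, cutoff,
                       as.integer(maxTrials), as.integer(n))
}

#' Propagate one streamline from a seed point
#'
#' Tracks bidirectionally: an initial orientation is drawn without cone
#' restriction and used for both launch directions; each half-track steps
#' along circular arcs of fixed arc length whose chord is
#' \code{2 (step/theta) sin(theta/2)} for turning angle theta, terminating
#' on grid exit, termination signal, or arc length beyond
#' \code{maxLengthMm}. The streamline is rejected (NULL) when it has fewer
#' than \code{minPoints} points.
#'
#' @param seedPoint world-mm coordinate inside the grid.
#' @param field an [OrientationField-class].
#' @param params a [TrackingParams-class].
#' @return an n x 3 matrix of points, or NULL on rejection.
#' @export
propagateStreamline <- function(seedPoint, field, params = trackingParams()) {
  wv <- worldToVoxel(matrix(seedPoint, ncol = 3), field@grid)
  if (!wv$inside) stop("propagateStreamline: seed outside grid")
  res <- resolveTrackingParams(mean(voxelSize(field@grid)), params)
  fa <- .fieldArgs(field)
  out <- .cppTrack(fa$dims, fa$invAffine, fa$offsets, fa$dirs, fa$amps,
                   matrix(as.numeric(seedPoint), ncol = 3), res$stepMm,
                   res$maxAngleDeg, params@cutoff, params@maxLengthMm,
                   params@minPoints, params@maxTrials)
  if (length(out) == 0L) NULL else out[[1]]
}

#' Track from every voxel of a seed mask
#'
#' Places \code{seedsPerVoxel} seed points uniformly at random inside each
#' seed voxel's cube and propagates each bidirectionally; rejected
#' streamlines (seed voxel below cutoff, too few points) are dropped.
#' Deterministic given the RNG state (\code{set.seed}).
#'
#' @param seedMask a [BinaryMask-class] on the field's grid.
#' @param field an [OrientationField-class].
#' @param params a [TrackingParams-class].
#' @param name label of the returned tractogram.
#' @return a [Tractogram-class].
#' @export
trackFromSeedMask <- function(seedMask, field, params = trackingParams(),
                              name = "tracked") {
  g <- field@grid
  if (!identical(seedMask@grid@dim, g@dim) ||
      max(abs(seedMask@grid@affine - g@affine)) > 1e-9)
    stop("trackFromSeedMask: seed mask and field must share one grid")
  vox <- which(seedMask@values == 1)
  if (length(vox) == 0L) stop("trackFromSeedMask: empty seed mask")
  idx <- allVoxelIndices(g)[vox, , drop = FALSE]
  k <- params@seedsPerVoxel
  cidx <- idx[rep(seq_len(nrow(idx)), each = k), , drop = FALSE] +
    matrix(runif(3L * nrow(idx) * k, -0.5, 0.5), ncol = 3)
  seeds <- voxelToWorld(cidx, g)
  res <- resolveTrackingParams(mean(voxelSize(g)), params)
  fa <- .fieldArgs(field)
  sl <- .cppTrack(fa$dims, fa$invAffine, fa$offsets, fa$dirs, fa$amps,
                  seeds, res$stepMm, res$maxAngleDeg, params@cutoff,
                  params@maxLengthMm, params@minPoints, params@maxTrials)
  new("Tractogram", streamlines = sl, grid = g, name = name)
}
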