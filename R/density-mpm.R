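# Track-density mapping, ROI-restricted connectivity clusters, relative
# thresholding, group maximum probability maps, and the percentage-overlap
# statistic.

#' Track-density map of a tractogram
#'
#' For each streamline the set of voxels its densified polyline visits
#' (sampling at most half the smallest voxel edge apart) is computed; each
#' voxel is counted once per streamline, so the map value is the number of
#' distinct streamlines visiting the voxel.
#'
#' @param tract a [Tractogram-class] (empty allowed, giving a zero map).
#' @param grid target [ImageGrid-class] (default: the tractogram's grid).
#' @return a [DensityMap-class].
#' @export
trackDensityMap <- function(tract, grid = NULL) {
  if (is.null(grid)) grid <- tract@grid
  h <- min(voxelSize(grid)) / 2
  counts <- numeric(prod(grid@dim))
  for (s in tract@streamlines) {
    wv <- worldToVoxel(densifyPolyline(s, h), grid)
    id <- wv$index[wv$inside, , drop = FALSE]
    if (nrow(id) == 0L) next
    lin <- unique(id[, 1] + grid@dim[1] * (id[, 2] + grid@dim[2] * id[, 3]) + 1)
    counts[lin] <- counts[lin] + 1
  }
  new("DensityMap", grid = grid, values = array(counts, grid@dim),
      bundle = tract@name, subject = "")
}

#' Restrict a density map to an ROI
#'
#' Voxelwise product with a binary mask: retains pallidal voxels connected
#' to the tract, zeroing everything else.
#'
#' @param density a [DensityMap-class].
#' @param roi a [BinaryMask-class] on the same grid.
#' @return a [DensityMap-class] with support inside the ROI.
#' @export
maskDensity <- function(density, roi) {
  if (!identical(density@grid@dim, roi@grid@dim) ||
      max(abs(density@grid@affine - roi@grid@affine)) > 1e-9)
    stop("maskDensity: density and ROI must share one grid")
  new("DensityMap", grid = density@grid,
      values = density@values * roi@values,
      bundle = density@bundle, subject = density@subject)
}

#' Relative threshold of a density map
#'
#' Retains voxels with value at least \code{fraction} times the map
#' maximum, ruling out low track-density voxels; an all-zero map gives an
#' all-zero mask. The referent of the fraction is the per-map maximum.
#'
#' @param density a [DensityMap-class] (or any [Volume-class]).
#' @param fraction threshold fraction in (0, 1), default 0.25.
#' @return a [BinaryMask-class].
#' @export
thresholdRelative <- function(density, fraction = 0.25) {
  if (fraction <= 0 || fraction >= 1)
    stop("thresholdRelative: fraction must lie in (0, 1)")
  mx <- max(density@values)
  if (mx <= 0) return(binaryMask(density@grid, 0))
  binaryMask(density@grid,
             array(as.double(density@values >= fraction * mx),
                   density@grid@dim))
}

#' Group maximum probability map
#'
#' Voxelwise sum of per-subject binary maps; the retained mask keeps voxels
#' covered by at least \code{ceiling(retentionFraction x N)} subjects
#' ("at least half of the sample" at the default 0.5).
#'
#' @param masks list of at least two [BinaryMask-class] on one grid.
#' @param retentionFraction retention fraction in (0, 1], default 0.5.
#' @return an [MPMap-class]; its \code{mpmMask()} is the retained mask.
#' @export
maximumProbabilityMap <- function(masks, retentionFraction = 0.5) {
  if (length(masks) < 2L)
    stop("maximumProbabilityMap: need at least 2 masks")
  g <- masks[[1]]@grid
  for (m in masks)
    if (!identical(m@grid@dim, g@dim) ||
        max(abs(m@grid@affine - g@affine)) > 1e-9)
      stop("maximumProbabilityMap: all masks must share one grid")
  counts <- Reduce(`+`, lapply(masks, slot, "values"))
  n <- length(masks)
  cut <- ceiling(retentionFraction * n)
  mask <- binaryMask(g, array(as.double(counts >= cut), g@dim))
  new("MPMap", grid = g, values = counts, nSubjects = as.integer(n),
      retentionFraction = retentionFraction, mask = mask)
}

#' Retained mask of an MPM
#' @param mpm an [MPMap-class].
#' @return the thresholded [BinaryMask-class].
#' @export
mpmMask <- function(mpm) mpm@mask

setMethod("show", "MPMap", function(object) {
  cat("MPMap: N =", object@nSubjects, "| retention >=",
      ceiling(object@retentionFraction * object@nSubjects),
      "subjects | retained voxels:", maskVolume(object@mask), "\n")
})

#' Percentage overlap of two binary masks
#'
#' \code{100 x |A intersect B| / |B|}, volumes in voxels. A is the
#' tract-derived (PPN-connected) MPM mask, B the functional-territory MPM
#' mask. Not symmetric in its arguments.
#'
#' @param A,B [BinaryMask-class] on one grid; \code{|B| > 0}.
#' @return percent overlap in [0, 100].
#' @examples
#' g <- imageGrid(c(4L, 1L, 1L), 1)
#' A <- binaryMask(g, array(c(1, 1, 0, 0), c(4, 1, 1)))
#' B <- binaryMask(g, array(c(1, 1, 1, 1), c(4, 1, 1)))
#' percentageOverlap(A, B)  # 50
#' @export
percentageOverlap <- function(A, B) {
  if (!identical(A@grid@dim, B@grid@dim) ||
      max(abs(A@grid@affine - B@grid@affine)) > 1e-9)
    stop("percentageOverlap: masks must share one grid")
  nb <- sum(B@values)
  if (nb == 0) stop("percentageOverlap: |B| = 0, overlap undefined")
  100 * sum(A@values * B@values) / nb
}

#' Subject-level PPN connectivity cluster on the template grid
#'
#' Composition in the fixed order: track-density map in subject space,
#' multiplied by the pallidal ROI, thresholded at \code{fraction} of the
#' map maximum, then registered to the template grid (nearest-neighbour).
#' Group-level clusters are obtained by passing the per-subject results to
#' [maximumProbabilityMap()].
#'
#' @param tract the selected bundle [Tractogram-class] (subject space).
#' @param roi the pallidal [BinaryMask-class] (subject space).
#' @param transform subject-to-template [AffineTransform-class].
#' @param templateGrid the template [ImageGrid-class].
#' @param fraction relative density threshold (default 0.25).
#' @return a [BinaryMask-class] on the template grid.
#' @export
subjectConnectivityCluster <- function(tract, roi, transform, templateGrid,
                                       fraction = 0.25) {
  d <- trackDensityMap(tract, roi@grid)
  d <- maskDensity(d, roi)
  m <- thresholdRelative(d, fraction)
  applyTransform(m, transform, templateGrid)
}

#' Group tract MPM from subject-space density maps
#'
#' Step order used for whole-tract group maps: register each subject's
#' density map to the template (nearest-neighbour), binarize, then sum into
#' an MPM.
#'
#' @param densities list of subject-space [DensityMap-class].
#' @param transforms list of subject-to-template [AffineTransform-class].
#' @param templateGrid template [ImageGrid-class].
#' @param retentionFraction MPM retention fraction (default 0.5).
#' @return an [MPMap-class].
#' @export
tractMpm <- function(densities, transforms, templateGrid,
                     retentionFraction = 0.5) {
  masks <- mapply(function(d, tr)
    binarize(applyTransform(d, tr, templateGrid)),
    densities, transforms, SIMPLIFY = FALSE)
  maximumProbabilityMap(masks, retentionFraction)
}
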