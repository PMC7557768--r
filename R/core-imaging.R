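# Grids, coordinate transforms, volumes, masks, streamline containers.

#' Construct an ImageGrid
#'
#' @param dim integer(3), voxels per axis.
#' @param voxelSize numeric(3) or scalar, voxel edge length in mm. Ignored
#'   when \code{affine} is given.
#' @param affine optional 4x4 voxel-to-world matrix. Default: diagonal
#'   scaling by \code{voxelSize} with the world origin at the grid centre.
#' @return an [ImageGrid-class].
#' @examples
#' g <- imageGrid(c(40L, 48L, 32L), 1.25)
#' voxelSize(g)
#' @export
imageGrid <- function(dim, voxelSize = c(1, 1, 1), affine = NULL) {
  dim <- as.integer(dim)
  if (is.null(affine)) {
    vs <- rep_len(as.numeric(voxelSize), 3L)
    affine <- diag(c(vs, 1))
    affine[1:3, 4] <- -vs * (dim - 1) / 2
  }
  new("ImageGrid", dim = dim, affine = affine)
}

#' Construct a Volume
#' @param grid an [ImageGrid-class].
#' @param values numeric array shaped like \code{gridDim(grid)}; a scalar is
#'   recycled.
#' @return a [Volume-class].
#' @export
volume <- function(grid, values = 0) {
  if (length(values) == 1L) values <- array(values, grid@dim)
  storage.mode(values) <- "double"
  new("Volume", grid = grid, values = values)
}

#' Construct a BinaryMask
#' @param grid an [ImageGrid-class].
#' @param values array of 0/1 values (scalar recycled).
#' @return a [BinaryMask-class].
#' @export
binaryMask <- function(grid, values = 0) {
  if (length(values) == 1L) values <- array(values, grid@dim)
  storage.mode(values) <- "double"
  new("BinaryMask", grid = grid, values = values)
}

#' Construct an AffineTransform
#' @param matrix 4x4 world-to-world matrix.
#' @return an [AffineTransform-class].
#' @export
affineTransform <- function(matrix) new("AffineTransform", matrix = matrix)

#' Construct a Tractogram
#' @param streamlines list of n x 3 world-mm matrices (n >= 2).
#' @param grid reference [ImageGrid-class].
#' @param name nonempty label.
#' @return a [Tractogram-class].
#' @export
tractogram <- function(streamlines, grid, name = "tract") {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "double"; s
  })
  new("Tractogram", streamlines = streamlines, grid = grid, name = name)
}

#' @describeIn gridDim grid dimensions of an ImageGrid
#' @export
setMethod("gridDim", "ImageGrid", function(x) x@dim)
#' @describeIn gridDim grid dimensions of a Volume
#' @export
setMethod("gridDim", "Volume", function(x) x@grid@dim)
#' @describeIn gridDim grid dimensions of a Tractogram's reference grid
#' @export
setMethod("gridDim", "Tractogram", function(x) x@grid@dim)

#' @describeIn voxelSize voxel size of an ImageGrid
#' @export
setMethod("voxelSize", "ImageGrid",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))
#' @describeIn voxelSize voxel size of a Volume's grid
#' @export
setMethod("voxelSize", "Volume", function(x) voxelSize(x@grid))

#' @describeIn affine affine of an ImageGrid
#' @export
setMethod("affine", "ImageGrid", function(x) x@affine)
#' @describeIn affine matrix of an AffineTransform
#' @export
setMethod("affine", "AffineTransform", function(x) x@matrix)
#' @describeIn affine affine of a Volume's grid
#' @export
setMethod("affine", "Volume", function(x) x@grid@affine)

#' @describeIn values values array of a Volume
#' @export
setMethod("values", "Volume", function(x) x@values)

#' @describeIn streamlines streamline list of a Tractogram
#' @export
setMethod("streamlines", "Tractogram", function(x) x@streamlines)
#' @describeIn streamlines selected streamlines of a BundleResult
#' @export
setMethod("streamlines", "BundleResult", function(x) x@tractogram@streamlines)

#' @describeIn nStreamlines NOS of a Tractogram
#' @export
setMethod("nStreamlines", "Tractogram",
          function(x) length(x@streamlines))
#' @describeIn nStreamlines NOS of a BundleResult
#' @export
setMethod("nStreamlines", "BundleResult", function(x) x@nos)

setMethod("show", "ImageGrid", function(object) {
  cat("ImageGrid:", paste(object@dim, collapse = " x "),
      "voxels,", paste(signif(voxelSize(object), 4), collapse = " x "),
      "mm\n")
})

setMethod("show", "Volume", function(object) {
  cat(class(object), ":", paste(object@grid@dim, collapse = " x "),
      "| range [", signif(min(object@values), 4), ",",
      signif(max(object@values), 4), "]\n")
})

setMethod("show", "Tractogram", function(object) {
  cat("Tractogram '", object@name, "': ", length(object@streamlines),
      " streamlines\n", sep = "")
})

setMethod("show", "BundleResult", function(object) {
  cat("BundleResult '", object@name, "': NOS = ", object@nos, " / ",
      object@nInput, " (rejected: ", object@rejectedInclude,
      " missed include, ", object@rejectedExclude, " hit exclude, ",
      object@rejectedSeed, " seed)\n", sep = "")
})

setMethod("show", "OrientationField", function(object) {
  nv <- prod(object@grid@dim)
  cat("OrientationField:", paste(object@grid@dim, collapse = " x "),
      "voxels,", object@offsets[nv + 1L], "lobes\n")
})

#' Map world-mm points to voxel indices
#'
#' Applies the inverse grid affine and assigns each point to the voxel that
#' owns it under the half-open convention: voxel \code{i} owns continuous
#' indices in \code{[i - 0.5, i + 0.5)} per axis (voxel centres at integer
#' indices). Points outside \code{[0, dim)} are marked out of grid.
#'
#' @param points n x 3 matrix (or length-3 vector) of world-mm coordinates.
#' @param grid an [ImageGrid-class].
#' @return a list with \code{index}, an n x 3 matrix of 0-based voxel
#'   indices (NA rows when out of grid), and \code{inside}, a logical
#'   vector.
#' @examples
#' g <- imageGrid(c(10L, 10L, 10L), 2)
#' ctr <- (affine(g) %*% c(0, 0, 0, 1))[1:3]
#' worldToVoxel(ctr, g)$index  # voxel (0, 0, 0)
#' @export
worldToVoxel <- function(points, grid) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (any(!is.finite(points)))
    stop("worldToVoxel: points must be finite")
  inv <- solve(grid@affine)
  cidx <- cbind(points, 1) %*% t(inv)
  idx <- floor(cidx[, 1:3, drop = FALSE] + 0.5)
  inside <- idx[, 1] >= 0 & idx[, 1] < grid@dim[1] &
    idx[, 2] >= 0 & idx[, 2] < grid@dim[2] &
    idx[, 3] >= 0 & idx[, 3] < grid@dim[3]
  idx[!inside, ] <- NA_real_
  list(index = idx, inside = inside)
}

#' World coordinates of voxel centres
#'
#' @param index n x 3 matrix of 0-based voxel indices.
#' @param grid an [ImageGrid-class].
#' @return n x 3 matrix of world-mm centre coordinates.
#' @export
voxelToWorld <- function(index, grid) {
  if (is.null(dim(index))) index <- matrix(index, ncol = 3)
  w <- cbind(index, 1) %*% t(grid@affine)
  w[, 1:3, drop = FALSE]
}

# 0-based index matrix of all voxels, column-major (x fastest)
allVoxelIndices <- function(grid) {
  d <- grid@dim
  cbind(rep(seq_len(d[1]) - 1L, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

#' @describeIn applyTransform pointwise mapping of a point matrix
#' @export
setMethod("applyTransform", "matrix",
          function(x, transform, targetGrid = NULL) {
  m <- transform@matrix
  out <- cbind(x, 1) %*% t(m)
  out[, 1:3, drop = FALSE]
})

#' @describeIn applyTransform pointwise mapping of every streamline
#' @export
setMethod("applyTransform", "Tractogram",
          function(x, transform, targetGrid = NULL) {
  g <- if (is.null(targetGrid)) x@grid else targetGrid
  sl <- lapply(x@streamlines, applyTransform, transform = transform)
  new("Tractogram", streamlines = sl, grid = g, name = x@name)
})

resampleNearest <- function(srcValues, srcGrid, transform, targetGrid) {
  ctr <- voxelToWorld(allVoxelIndices(targetGrid), targetGrid)
  back <- cbind(ctr, 1) %*% t(solve(transform@matrix))
  wv <- worldToVoxel(back[, 1:3, drop = FALSE], srcGrid)
  out <- numeric(nrow(ctr))
  ins <- wv$inside
  if (any(ins)) {
    id <- wv$index[ins, , drop = FALSE]
    lin <- id[, 1] + srcGrid@dim[1] * (id[, 2] + srcGrid@dim[2] * id[, 3]) + 1
    out[ins] <- srcValues[lin]
  }
  array(out, targetGrid@dim)
}

#' @describeIn applyTransform nearest-neighbour resampling of a Volume
#' @export
setMethod("applyTransform", "Volume",
          function(x, transform, targetGrid = NULL) {
  if (is.null(targetGrid)) targetGrid <- x@grid
  volume(targetGrid, resampleNearest(x@values, x@grid, transform, targetGrid))
})

#' @describeIn applyTransform nearest-neighbour resampling of a BinaryMask
#' @export
setMethod("applyTransform", "BinaryMask",
          function(x, transform, targetGrid = NULL) {
  if (is.null(targetGrid)) targetGrid <- x@grid
  binaryMask(targetGrid,
             resampleNearest(x@values, x@grid, transform, targetGrid))
})

#' @describeIn binarize strictly-positive thresholding of a Volume
#' @export
setMethod("binarize", "Volume", function(x) {
  binaryMask(x@grid, array(as.double(x@values > 0), x@grid@dim))
})

#' Voxelwise mask lookup for world points
#'
#' @param points n x 3 world-mm matrix.
#' @param mask a [BinaryMask-class].
#' @return logical vector: TRUE where the owning voxel has value 1.
#' @keywords internal
pointsInMask <- function(points, mask) {
  wv <- worldToVoxel(points, mask@grid)
  out <- logical(nrow(points))
  ins <- wv$inside
  if (any(ins)) {
    id <- wv$index[ins, , drop = FALSE]
    lin <- id[, 1] + mask@grid@dim[1] * (id[, 2] + mask@grid@dim[2] * id[, 3]) + 1
    out[ins] <- mask@values[lin] == 1
  }
  out
}

#' Densify a polyline at a maximum spacing
#'
#' Subdivides each segment into \code{ceiling(length / spacing)} equal parts
#' (endpoints included once). This is the voxel-visitation contract used by
#' [streamlineIntersects()] and [trackDensityMap()]: with spacing equal to
#' half the smallest voxel edge, no voxel whose intersection chord exceeds
#' half a voxel can be skipped, so thin masks such as a one-slice midline
#' slab cannot be tunnelled through.
#'
#' @param points n x 3 matrix.
#' @param spacing maximum inter-sample distance (mm).
#' @return m x 3 matrix of densified points (m >= n).
#' @export
densifyPolyline <- function(points, spacing) {
  n <- nrow(points)
  if (n < 2L) return(points)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / spacing))
    t <- seq(0, 1, length.out = k + 1L)
    if (i < n - 1L) t <- t[-(k + 1L)]  # avoid duplicating interior vertices
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Voxel-count volume of a mask
#' @param mask a [BinaryMask-class].
#' @return number of voxels with value 1.
#' @export
maskVolume <- function(mask) sum(mask@values)
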