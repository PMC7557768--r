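#' Grid dimensions
#' @param x an object with an [ImageGrid-class].
#' @return integer(3) voxels per axis.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Voxel size in millimetres
#'
#' Column norms of the 3x3 block of the voxel-to-world affine.
#' @param x an object with an [ImageGrid-class].
#' @return numeric(3) voxel edge lengths (mm).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Voxel-to-world affine
#' @param x an object with an [ImageGrid-class] or an
#'   [AffineTransform-class].
#' @return 4x4 numeric matrix.
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' Voxel values
#' @param x a [Volume-class] (or subclass).
#' @return the numeric 3-D array.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Streamlines of a tractogram
#' @param x a [Tractogram-class] or [BundleResult-class].
#' @return list of n x 3 matrices (world mm).
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' Number of streamlines (NOS)
#' @param x a [Tractogram-class] or [BundleResult-class].
#' @return integer streamline count.
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))

#' Apply an affine spatial transform
#'
#' Maps an object from one world space to another. Streamline points are
#' mapped pointwise; volumes and binary masks are resampled onto
#' \code{targetGrid} by nearest neighbour: each target voxel takes the value
#' of the source voxel that owns its back-transformed centre (zero outside
#' the source grid). Nearest-neighbour resampling keeps mask values in
#' \{0, 1\}.
#'
#' @param x a [Tractogram-class], [Volume-class], [BinaryMask-class] or an
#'   n x 3 matrix of world-mm points.
#' @param transform an [AffineTransform-class].
#' @param targetGrid the [ImageGrid-class] of the output (ignored for
#'   streamlines/points).
#' @return the transformed object of the same class.
#' @examples
#' g <- imageGrid(c(5L, 5L, 5L), c(1, 1, 1))
#' m <- binaryMask(g, array(0, c(5, 5, 5)))
#' identityT <- affineTransform(diag(4))
#' m2 <- applyTransform(m, identityT, g)
#' stopifnot(identical(values(m2), values(m)))
#' @export
setGeneric("applyTransform",
           function(x, transform, targetGrid = NULL)
             standardGeneric("applyTransform"))

#' Binarize a volume
#'
#' Value 1 where the input is strictly positive, 0 elsewhere. Idempotent.
#' @param x a [Volume-class].
#' @return a [BinaryMask-class] on the same grid.
#' @export
setGeneric("binarize", function(x) standardGeneric("binarize"))
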