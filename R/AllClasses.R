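#' @useDynLib ppntract, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rpois runif rnorm sd pnorm qnorm quantile
#' @importFrom utils write.csv read.csv
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ImageGrid: a 3-D voxel lattice with a voxel-to-world affine
#'
#' An \code{ImageGrid} defines the sampling lattice shared by volumes, masks
#' and orientation fields: the number of voxels per axis and a 4x4 affine
#' mapping 0-based voxel indices to world coordinates in millimetres. Voxel
#' centres sit at integer indices; each voxel owns the half-open cube
#' \code{[i - 0.5, i + 0.5)} per axis in continuous index space.
#'
#' @slot dim integer(3), voxels per axis.
#' @slot affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#'
#' @seealso [imageGrid()], [worldToVoxel()], [voxelSize()]
#' @export
setClass("ImageGrid", representation(dim = "integer", affine = "matrix"))

setValidity("ImageGrid", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be 3 positive integers")
  a <- object@affine
  if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)) || any(!is.finite(a)))
    return("affine must be a finite 4x4 numeric matrix")
  if (max(abs(a[4, ] - c(0, 0, 0, 1))) > 1e-12)
    return("affine bottom row must be (0, 0, 0, 1)")
  if (abs(det(a[1:3, 1:3])) < 1e-12)
    return("affine must be invertible")
  TRUE
})

#' Volume: scalar values on an ImageGrid
#'
#' @slot grid an [ImageGrid-class].
#' @slot values numeric 3-D array with \code{dim(values) == gridDim(grid)},
#'   all finite.
#'
#' @seealso [volume()], [binarize()]
#' @export
setClass("Volume", representation(grid = "ImageGrid", values = "array"))

setValidity("Volume", function(object) {
  if (!identical(dim(object@values), object@grid@dim))
    return("values shape must equal grid dim")
  if (any(!is.finite(object@values)))
    return("all values must be finite")
  TRUE
})

#' BinaryMask: a \{0, 1\} label volume
#'
#' A \code{Volume} whose values are exactly 0 or 1; used for ROIs
#' (seed/include regions), ROAs (exclusion regions), the midsagittal slab,
#' functional-territory sub-masks, and thresholded maps.
#'
#' @seealso [binaryMask()], [binarize()], [maskVolume()]
#' @export
setClass("BinaryMask", contains = "Volume")

setValidity("BinaryMask", function(object) {
  v <- object@values
  if (any(v != 0 & v != 1))
    return("mask values must be exactly 0 or 1")
  TRUE
})

#' AffineTransform: world-mm to world-mm affine map
#'
#' Represents a subject-to-template (or arbitrary) affine spatial transform.
#'
#' @slot matrix 4x4 numeric, bottom row (0,0,0,1), invertible.
#' @export
setClass("AffineTransform", representation(matrix = "matrix"))

setValidity("AffineTransform", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)) || any(!is.finite(m)))
    return("matrix must be a finite 4x4 numeric matrix")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    return("bottom row must be (0, 0, 0, 1)")
  if (abs(det(m[1:3, 1:3])) < 1e-12)
    return("transform must be invertible")
  TRUE
})

#' Tractogram: a set of world-space streamlines
#'
#' Streamlines are ordered polylines in world millimetres (the TCK
#' convention), stored as n x 3 matrices. The reference grid records the
#' lattice on which the tractogram was generated or is to be voxelised.
#' The number of streamlines (NOS) is the quantitative connectivity proxy
#' extracted from selected bundles.
#'
#' @slot streamlines list of numeric matrices, each n x 3 with n >= 2 and all
#'   coordinates finite.
#' @slot grid the reference [ImageGrid-class].
#' @slot name nonempty character label.
#'
#' @seealso [tractogram()], [nStreamlines()], [readTck()], [writeTck()]
#' @export
setClass("Tractogram",
         representation(streamlines = "list", grid = "ImageGrid",
                        name = "character"))

setValidity("Tractogram", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a nonempty string")
  for (s in object@streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
      return("each streamline must be an n x 3 matrix with n >= 2")
    if (any(!is.finite(s)))
      return("streamline coordinates must be finite")
  }
  TRUE
})

#' OrientationField: discrete fiber-orientation lobes per voxel
#'
#' A compact stand-in for fiber orientation distribution functions: each
#' voxel holds zero or more lobes, a unit direction plus a nonnegative
#' amplitude, with antipodal symmetry assumed (d and -d are the same
#' orientation). Lobes are stored in compressed form: \code{offsets} has
#' length \code{prod(dim) + 1}; the lobes of voxel with 0-based linear index
#' \code{v} (column-major, x fastest) are rows
#' \code{(offsets[v + 1] + 1):offsets[v + 2]} of \code{directions} /
#' elements of \code{amplitudes}.
#'
#' @slot grid the [ImageGrid-class].
#' @slot offsets integer vector of per-voxel lobe offsets (CSR layout).
#' @slot directions L x 3 numeric matrix of unit directions.
#' @slot amplitudes numeric vector of length L, finite and >= 0.
#'
#' @seealso [orientationField()], [generateOrientationField()],
#'   [sampleTrackingDirection()]
#' @export
setClass("OrientationField",
         representation(grid = "ImageGrid", offsets = "integer",
                        directions = "matrix", amplitudes = "numeric"))

setValidity("OrientationField", function(object) {
  nv <- prod(object@grid@dim)
  if (length(object@offsets) != nv + 1L || object@offsets[1] != 0L)
    return("offsets must have length prod(dim)+1 and start at 0")
  if (is.unsorted(object@offsets))
    return("offsets must be nondecreasing")
  L <- object@offsets[nv + 1L]
  if (nrow(object@directions) != L || length(object@amplitudes) != L)
    return("directions/amplitudes length must match final offset")
  if (L > 0) {
    nrm <- sqrt(rowSums(object@directions^2))
    if (max(abs(nrm - 1)) > 1e-6)
      return("all lobe directions must be unit-norm within 1e-6")
    if (any(!is.finite(object@amplitudes)) || any(object@amplitudes < 0))
      return("amplitudes must be finite and >= 0")
  }
  TRUE
})

#' TrackingParams: probabilistic tracking parameterization
#'
#' Step size and maximum turning angle are resolved from the voxel size:
#' step = stepFactor x voxel size, max angle = angleFactorDeg x step / voxel
#' size, so with the default factors (1.25, 30) the angle is 37.5 degrees at
#' any isotropic resolution. Propagation terminates where no lobe amplitude
#' reaches \code{cutoff}.
#'
#' @slot seedsPerVoxel integer >= 1 seed points per seed-mask voxel.
#' @slot stepFactor step size as a multiple of voxel size (default 1.25).
#' @slot angleFactorDeg angle factor in degrees (default 30).
#' @slot cutoff minimum lobe amplitude to continue (default 0.025).
#' @slot maxLengthMm maximum half-track arc length in mm.
#' @slot minPoints minimum number of points for a streamline to be kept.
#' @slot maxTrials rejection-sampling trial budget per step.
#'
#' @seealso [trackingParams()], [resolveTrackingParams()]
#' @export
setClass("TrackingParams",
         representation(seedsPerVoxel = "integer", stepFactor = "numeric",
                        angleFactorDeg = "numeric", cutoff = "numeric",
                        maxLengthMm = "numeric", minPoints = "integer",
                        maxTrials = "integer"))

setValidity("TrackingParams", function(object) {
  if (object@seedsPerVoxel < 1L) return("seedsPerVoxel must be >= 1")
  if (object@stepFactor <= 0) return("stepFactor must be > 0")
  ang <- object@angleFactorDeg * object@stepFactor
  if (ang <= 0 || ang >= 90)
    return("resolved max angle must lie in (0, 90) degrees")
  if (object@cutoff <= 0 || object@cutoff >= 1)
    return("cutoff must lie in (0, 1)")
  if (object@maxLengthMm <= 0) return("maxLengthMm must be > 0")
  if (object@minPoints < 2L) return("minPoints must be >= 2")
  if (object@maxTrials < 1L) return("maxTrials must be >= 1")
  TRUE
})

#' SelectionSpec: seed / include / exclude definition of one bundle
#'
#' Mirrors ROI-based tract segmentation: a streamline is kept when it starts
#' in (or touches, see [selectBundle()]) the seed mask, intersects every
#' include mask, and touches no exclude mask.
#'
#' @slot name bundle label, e.g. \code{"L_GPi_ipsi"}.
#' @slot seed seed [BinaryMask-class].
#' @slot include list of include masks (all must be visited).
#' @slot exclude list of exclusion masks (none may be touched).
#' @export
setClass("SelectionSpec",
         representation(name = "character", seed = "BinaryMask",
                        include = "list", exclude = "list"))

setValidity("SelectionSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a nonempty string")
  g <- object@seed@grid
  allm <- c(object@include, object@exclude)
  for (m in allm) {
    if (!is(m, "BinaryMask")) return("include/exclude must be BinaryMask")
    if (!identical(m@grid@dim, g@dim) ||
        max(abs(m@grid@affine - g@affine)) > 1e-9)
      return("all masks must share one grid")
  }
  for (m in object@exclude) {
    if (any(object@seed@values == 1 & m@values == 1))
      return("seed mask must not overlap any exclude mask")
  }
  TRUE
})

#' BundleResult: outcome of applying a SelectionSpec to a tractogram
#'
#' @slot name the spec name.
#' @slot tractogram the selected streamlines.
#' @slot nos number of selected streamlines.
#' @slot rejectedInclude streamlines discarded for missing an include mask.
#' @slot rejectedExclude streamlines discarded for touching an exclude mask.
#' @slot rejectedSeed streamlines discarded for failing the seed check.
#' @slot nInput number of input streamlines.
#' @export
setClass("BundleResult",
         representation(name = "character", tractogram = "Tractogram",
                        nos = "integer", rejectedInclude = "integer",
                        rejectedExclude = "integer", rejectedSeed = "integer",
                        nInput = "integer"))

setValidity("BundleResult", function(object) {
  if (object@nos != length(object@tractogram@streamlines))
    return("nos must equal the selected streamline count")
  if (object@nos + object@rejectedInclude + object@rejectedExclude +
        object@rejectedSeed != object@nInput)
    return("kept + rejected must equal the input count")
  TRUE
})

#' DensityMap: per-voxel distinct-streamline counts
#'
#' Track-density map: each voxel stores the number of distinct streamlines
#' whose densified polyline visits it.
#'
#' @slot bundle provenance bundle name.
#' @slot subject provenance subject label.
#' @seealso [trackDensityMap()]
#' @export
setClass("DensityMap", contains = "Volume",
         representation(bundle = "character", subject = "character"))

#' MPMap: group maximum probability map
#'
#' Per-voxel count of subjects whose binarized map covers the voxel, together
#' with the retained mask at the "at least half of the sample" cut
#' (count >= ceiling(retentionFraction x nSubjects)).
#'
#' @slot nSubjects number of contributing subjects N.
#' @slot retentionFraction retention fraction (default 0.5).
#' @slot mask the thresholded [BinaryMask-class].
#' @seealso [maximumProbabilityMap()]
#' @export
setClass("MPMap", contains = "Volume",
         representation(nSubjects = "integer", retentionFraction = "numeric",
                        mask = "BinaryMask"))

setValidity("MPMap", function(object) {
  if (any(object@values > object@nSubjects))
    return("counts must not exceed nSubjects")
  if (object@retentionFraction <= 0 || object@retentionFraction > 1)
    return("retentionFraction must lie in (0, 1]")
  TRUE
})

#' BundleSpec: ground-truth bundle definition for the phantom
#'
#' A smooth centerline through >= 3 control points (world mm), an expected
#' streamline count, per-streamline control-point jitter, and a relative
#' tube-thickness multiplier that shapes the orientation-field tube.
#'
#' @slot name bundle name.
#' @slot controlPoints k x 3 matrix of world-mm control points (k >= 3).
#' @slot nTrue expected (pre-multiplier) streamline count, >= 0.
#' @slot dispersionMm per-streamline isotropic control-point jitter (mm).
#' @slot crossesMidline logical flag.
#' @slot countMultiplier product of segment/lateralization effect multipliers.
#' @slot seedRoi name of the ROI the bundle starts in (selection seed side).
#' @slot targetRoi name of the ROI/region the bundle ends in.
#' @export
setClass("BundleSpec",
         representation(name = "character", controlPoints = "matrix",
                        nTrue = "numeric", dispersionMm = "numeric",
                        crossesMidline = "logical",
                        countMultiplier = "numeric",
                        seedRoi = "character", targetRoi = "character"))

setValidity("BundleSpec", function(object) {
  if (nrow(object@controlPoints) < 3L || ncol(object@controlPoints) != 3L)
    return("controlPoints must be a k x 3 matrix with k >= 3")
  if (object@nTrue < 0) return("nTrue must be >= 0")
  if (object@dispersionMm < 0) return("dispersionMm must be >= 0")
  if (object@countMultiplier <= 0) return("countMultiplier must be > 0")
  TRUE
})

#' PhantomConfig: synthetic-cohort generator configuration
#'
#' Describes the template-space geometry (spherical ROIs for pallidal
#' segments, PPN, exclusion nuclei; midsagittal slab), the six
#' pallidotegmental bundles plus distractors, the functional-territory
#' tri-section of each pallidal ROI, the built-in effect sizes
#' (GPi over GPe, right over left, contralateral factors), per-subject rigid
#' jitter bounds, and the master seed. See [phantomConfig()] for defaults
#' and their rationale.
#'
#' @slot grid template [ImageGrid-class].
#' @slot rois named list: each element \code{list(center = world mm,
#'   radiusMm = numeric)} for spherical ROIs, or \code{list(slab = TRUE,
#'   thicknessVox = integer)} for the midline slab.
#' @slot bundles named list of [BundleSpec-class].
#' @slot territoryAxis numeric(3): direction (world) from limbic
#'   (anteroventral) to sensorimotor (posterodorsal) along which pallidal
#'   ROIs are tri-sected.
#' @slot gpiOverGpeRatio expected-count ratio GPi/GPe (default 2).
#' @slot rightOverLeftRatio expected-count ratio right/left (default 1.25).
#' @slot contraLeftFactor left contralateral over left GPi-ipsi (default 1.25).
#' @slot contraRightFactor right contralateral over right GPi-ipsi
#'   (default 0.875).
#' @slot maxTranslationMm rigid jitter translation bound.
#' @slot maxRotationDeg rigid jitter rotation bound.
#' @slot masterSeed integer master seed.
#' @slot plantedTerritory territory the GPi bundles terminate in
#'   ("limbic", "associative" or "sensorimotor").
#' @export
setClass("PhantomConfig",
         representation(grid = "ImageGrid", rois = "list", bundles = "list",
                        territoryAxis = "numeric",
                        gpiOverGpeRatio = "numeric",
                        rightOverLeftRatio = "numeric",
                        contraLeftFactor = "numeric",
                        contraRightFactor = "numeric",
                        maxTranslationMm = "numeric",
                        maxRotationDeg = "numeric",
                        masterSeed = "integer",
                        plantedTerritory = "character"))

setValidity("PhantomConfig", function(object) {
  if (object@gpiOverGpeRatio <= 0 || object@rightOverLeftRatio <= 0 ||
      object@contraLeftFactor <= 0 || object@contraRightFactor <= 0)
    return("all ratio knobs must be > 0")
  if (object@maxTranslationMm < 0 || object@maxRotationDeg < 0)
    return("jitter bounds must be >= 0")
  if (!object@plantedTerritory %in%
        c("limbic", "associative", "sensorimotor"))
    return("plantedTerritory must be limbic, associative or sensorimotor")
  # spherical ROIs must lie inside the grid
  g <- object@grid
  inv <- solve(g@affine)
  for (nm in names(object@rois)) {
    r <- object@rois[[nm]]
    if (isTRUE(r$slab)) next
    cv <- (inv %*% c(r$center, 1))[1:3]
    rv <- r$radiusMm / voxelSize(g)
    if (any(cv - rv < -0.5) || any(cv + rv > g@dim - 0.5))
      return(sprintf("ROI '%s' does not lie inside the grid", nm))
  }
  TRUE
})

#' SyntheticSubject: one phantom subject with full ground truth
#'
#' @slot id subject label.
#' @slot masks named list of subject-space [BinaryMask-class] objects (ROIs,
#'   exclusion nuclei, midline slab, territory sub-masks).
#' @slot field the subject's [OrientationField-class].
#' @slot tractograms named list of ground-truth [Tractogram-class], one per
#'   bundle (including distractors).
#' @slot transform subject-to-template [AffineTransform-class] (inverse of
#'   the applied jitter).
#' @slot trueCounts named numeric: realized Poisson counts per bundle.
#' @slot grid the subject [ImageGrid-class] (same lattice as template).
#' @export
setClass("SyntheticSubject",
         representation(id = "character", masks = "list",
                        field = "OrientationField", tractograms = "list",
                        transform = "AffineTransform",
                        trueCounts = "numeric", grid = "ImageGrid"))

#' RunConfig: end-to-end pipeline configuration
#'
#' Holds the analysis thresholds (relative track-density cut, MPM retention
#' fraction, significance level), cohort size, tracking effort and the master
#' seed. Defaults follow the study conditions: density fraction 0.25, MPM
#' retention 0.50, alpha 0.05.
#'
#' @slot nSubjects cohort size (>= 2).
#' @slot seedsPerVoxel tracking seeds per seed-mask voxel.
#' @slot densityFraction relative track-density threshold in (0, 1).
#' @slot mpmFraction MPM retention fraction in (0, 1].
#' @slot alpha significance level in (0, 1).
#' @slot masterSeed integer master seed.
#' @slot outDir output directory for pipeline products.
#' @seealso [runConfig()], [loadRunConfig()], [runPipeline()]
#' @export
setClass("RunConfig",
         representation(nSubjects = "integer", seedsPerVoxel = "integer",
                        densityFraction = "numeric", mpmFraction = "numeric",
                        alpha = "numeric", masterSeed = "integer",
                        outDir = "character"))

setValidity("RunConfig", function(object) {
  if (object@nSubjects < 2L) return("nSubjects: cohort size must be >= 2")
  if (object@seedsPerVoxel < 1L) return("seedsPerVoxel must be >= 1")
  if (object@densityFraction <= 0 || object@densityFraction >= 1)
    return("densityFraction must lie in (0, 1)")
  if (object@mpmFraction <= 0 || object@mpmFraction > 1)
    return("mpmFraction must lie in (0, 1]")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  TRUE
})

#' PairedTestResult: Wilcoxon signed-rank test outcome
#'
#' @slot pair names of the two compared bundles.
#' @slot nTotal number of pairs supplied.
#' @slot nEffective pairs remaining after zero-difference removal.
#' @slot statistic W, the sum of positive-difference ranks.
#' @slot pValue two-sided p-value.
#' @slot method "exact" (full enumeration) or "normal-approximation".
#' @seealso [wilcoxonSignedRank()]
#' @export
setClass("PairedTestResult",
         representation(pair = "character", nTotal = "integer",
                        nEffective = "integer", statistic = "numeric",
                        pValue = "numeric", method = "character"))

setValidity("PairedTestResult", function(object) {
  wmax <- object@nEffective * (object@nEffective + 1) / 2
  if (object@statistic < 0 || object@statistic > wmax)
    return("W must lie in [0, n(n+1)/2]")
  if (object@pValue <= 0 || object@pValue > 1)
    return("p must lie in (0, 1]")
  TRUE
})
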