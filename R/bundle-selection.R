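# Seed/include/exclude bundle segmentation: keep streamlines that start in
# (or touch) the seed ROI, visit every include ROI, and touch no exclusion
# ROI; tally rejections and extract NOS.

#' Construct a SelectionSpec
#' @param name bundle label.
#' @param seed seed [BinaryMask-class].
#' @param include list of include masks.
#' @param exclude list of exclusion masks.
#' @return a [SelectionSpec-class].
#' @export
selectionSpec <- function(name, seed, include = list(), exclude = list()) {
  new("SelectionSpec", name = name, seed = seed, include = include,
      exclude = exclude)
}

setMethod("show", "SelectionSpec", function(object) {
  cat("SelectionSpec '", object@name, "': seed + ",
      length(object@include), " include + ", length(object@exclude),
      " exclude masks\n", sep = "")
})

#' Does a streamline intersect a mask?
#'
#' TRUE when any vertex, or any point of each inter-vertex chord sampled at
#' at most half-voxel spacing, falls in a voxel where the mask is 1. The
#' densification prevents tunnelling through masks as thin as one voxel
#' slice (e.g. a midsagittal slab).
#'
#' @param streamline n x 3 world-mm matrix.
#' @param mask a [BinaryMask-class].
#' @return logical scalar.
#' @export
streamlineIntersects <- function(streamline, mask) {
  h <- min(voxelSize(mask@grid)) / 2
  pts <- densifyPolyline(streamline, h)
  any(pointsInMask(pts, mask))
}

#' Select a bundle with seed/include/exclude logic
#'
#' Keeps exactly the streamlines that (a) pass the seed check, (b)
#' intersect every include mask, and (c) intersect no exclude mask, in
#' input order; rejection causes are tallied. With bidirectional tracking
#' the seed vertex lies inside the streamline, so the default seed check is
#' intersection with the seed mask; \code{seedCheck = "start"} requires the
#' first point to lie in the seed instead.
#'
#' @param tract a [Tractogram-class].
#' @param spec a [SelectionSpec-class].
#' @param seedCheck "intersect" (default) or "start".
#' @return a [BundleResult-class]; selection is a pure, idempotent filter.
#' @export
selectBundle <- function(tract, spec, seedCheck = c("intersect", "start")) {
  seedCheck <- match.arg(seedCheck)
  keep <- logical(length(tract@streamlines))
  rejSeed <- rejInc <- rejExc <- 0L
  g <- spec@seed@grid
  h <- min(voxelSize(g)) / 2
  for (i in seq_along(tract@streamlines)) {
    s <- tract@streamlines[[i]]
    # densify and map to voxel linear indices once; all masks share the grid
    wv <- worldToVoxel(densifyPolyline(s, h), g)
    id <- wv$index[wv$inside, , drop = FALSE]
    lin <- unique(id[, 1] + g@dim[1] * (id[, 2] + g@dim[2] * id[, 3]) + 1)
    touches <- function(m) any(m@values[lin] == 1)
    okSeed <- if (seedCheck == "start")
      pointsInMask(s[1, , drop = FALSE], spec@seed)
    else touches(spec@seed)
    if (!okSeed) { rejSeed <- rejSeed + 1L; next }
    hitExc <- FALSE
    for (m in spec@exclude)
      if (touches(m)) { hitExc <- TRUE; break }
    if (hitExc) { rejExc <- rejExc + 1L; next }
    okInc <- TRUE
    for (m in spec@include)
      if (!touches(m)) { okInc <- FALSE; break }
    if (!okInc) { rejInc <- rejInc + 1L; next }
    keep[i] <- TRUE
  }
  sel <- new("Tractogram", streamlines = tract@streamlines[keep],
             grid = tract@grid, name = spec@name)
  new("BundleResult", name = spec@name, tractogram = sel,
      nos = sum(keep), rejectedInclude = rejInc, rejectedExclude = rejExc,
      rejectedSeed = rejSeed, nInput = length(tract@streamlines))
}

#' Build the six pallidotegmental selection specs for a subject
#'
#' Per hemisphere: GPi-ipsilateral (seed GPi, include ipsilateral PPN,
#' exclude the other pallidal segment, the six ipsilateral exclusion nuclei
#' and the midline slab), GPe-ipsilateral (roles of GPi/GPe swapped), and
#' GPi-contralateral (seed GPi, include the contralateral PPN, exclude the
#' six contralateral nuclei; the midline slab is NOT excluded, since the
#' crossing is the point). No GPe-contralateral spec is produced: crossed
#' GPe-PPN connections are not reconstructed.
#'
#' @param masks named list of [BinaryMask-class]: \code{GPi_L/R},
#'   \code{GPe_L/R}, \code{PPN_L/R}, \code{caudate_}, \code{putamen_},
#'   \code{accumbens_}, \code{STN_}, \code{SNc_}, \code{SNr_} (L/R), and
#'   \code{midline}.
#' @param contralateralNuclei logical: additionally exclude the
#'   contralateral nuclei in the ipsilateral specs (default FALSE).
#' @return named list of six [SelectionSpec-class] objects:
#'   \code{L_GPi_ipsi}, \code{R_GPi_ipsi}, \code{L_GPe_ipsi},
#'   \code{R_GPe_ipsi}, \code{L_GPi_contra}, \code{R_GPi_contra}.
#' @export
buildPallidotegmentalSpecs <- function(masks, contralateralNuclei = FALSE) {
  nuclei <- c("caudate", "putamen", "accumbens", "STN", "SNc", "SNr")
  need <- c(paste0(rep(c("GPi", "GPe", "PPN", nuclei), each = 2),
                   c("_L", "_R")), "midline")
  miss <- setdiff(need, names(masks))
  if (length(miss) > 0L)
    stop("buildPallidotegmentalSpecs: missing mask(s): ",
         paste(miss, collapse = ", "))
  side <- function(h) paste0(nuclei, "_", h)
  specs <- list()
  for (h in c("L", "R")) {
    o <- if (h == "L") "R" else "L"
    ipsiNuc <- masks[side(h)]
    extra <- if (contralateralNuclei) masks[side(o)] else list()
    specs[[paste0(h, "_GPi_ipsi")]] <- selectionSpec(
      paste0(h, "_GPi_ipsi"),
      seed = masks[[paste0("GPi_", h)]],
      include = list(masks[[paste0("PPN_", h)]]),
      exclude = c(list(masks[[paste0("GPe_", h)]]), ipsiNuc, extra,
                  list(masks$midline)))
    specs[[paste0(h, "_GPe_ipsi")]] <- selectionSpec(
      paste0(h, "_GPe_ipsi"),
      seed = masks[[paste0("GPe_", h)]],
      include = list(masks[[paste0("PPN_", h)]]),
      exclude = c(list(masks[[paste0("GPi_", h)]]), ipsiNuc, extra,
                  list(masks$midline)))
    specs[[paste0(h, "_GPi_contra")]] <- selectionSpec(
      paste0(h, "_GPi_contra"),
      seed = masks[[paste0("GPi_", h)]],
      include = list(masks[[paste0("PPN_", o)]]),
      exclude = masks[side(o)])
  }
  specs[c("L_GPi_ipsi", "R_GPi_ipsi", "L_GPe_ipsi", "R_GPe_ipsi",
          "L_GPi_contra", "R_GPi_contra")]
}
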