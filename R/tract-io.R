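# File I/O: TCK tractograms, NIfTI-1 volumes, flat key/value run configs.
# All writers are deterministic (fixed header text, no timestamps) so that
# identical inputs give byte-identical files.

#' Write a tractogram in TCK format
#'
#' TCK (MRtrix dialect): a text header (magic line \code{mrtrix tracks},
#' \code{key: value} lines, \code{file: . <offset>}, \code{END}), followed by
#' little-endian float32 world-mm triples; streamlines are delimited by a
#' NaN triple and the stream is terminated by an Inf triple.
#'
#' @param tract a [Tractogram-class].
#' @param path output file path.
#' @param stepSizeMm optional step size recorded in the header.
#' @return \code{path}, invisibly.
#' @seealso [readTck()]
#' @export
writeTck <- function(tract, path, stepSizeMm = NA_real_) {
  lines <- c("mrtrix tracks",
             sprintf("count: %d", length(tract@streamlines)),
             "datatype: Float32LE")
  if (is.finite(stepSizeMm))
    lines <- c(lines, sprintf("step_size: %.6f", stepSizeMm))
  base <- paste0(paste(lines, collapse = "\n"), "\nfile: . ")
  tail <- "\nEND\n"
  # fixed point: offset value must account for its own digit count
  off <- nchar(base) + nchar(tail) + 1L
  repeat {
    total <- nchar(base) + nchar(as.character(off)) + nchar(tail)
    if (total == off) break
    off <- total
  }
  header <- paste0(base, off, tail)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in tract@streamlines) {
    writeBin(as.vector(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#'
#' @param path path to a TCK file.
#' @param grid reference [ImageGrid-class] to attach (TCK itself stores
#'   world-mm coordinates only). Default: a unit 1-voxel grid.
#' @param name tractogram label (default: file name).
#' @return a [Tractogram-class].
#' @seealso [writeTck()]
#' @export
readTck <- function(path, grid = NULL, name = NULL) {
  if (!file.exists(path)) stop("readTck: file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  # header is ASCII up to the END line; the binary payload that follows may
  # contain nul bytes, so locate "\nEND\n" on raw bytes before converting
  lim <- min(4096L, length(raw))
  marker <- charToRaw("\nEND\n")
  hdrEnd <- NA_integer_
  for (i in seq_len(max(0L, lim - 4L))) {
    if (raw[i] == marker[1] && all(raw[i:(i + 4L)] == marker)) {
      hdrEnd <- i + 4L
      break
    }
  }
  if (is.na(hdrEnd)) stop("readTck: header END marker not found")
  txt <- rawToChar(raw[seq_len(hdrEnd)])
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 1L || lines[1] != "mrtrix tracks")
    stop("readTck: bad magic line (expected 'mrtrix tracks')")
  offset <- NA_integer_
  datatype <- NA_character_
  count <- NA_integer_
  for (ln in lines[-1]) {
    if (ln == "END") break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) next
    key <- kv[2]; val <- kv[3]
    if (key == "datatype") datatype <- val
    if (key == "count") count <- as.integer(val)
    if (key == "file") {
      parts <- strsplit(val, " +")[[1]]
      offset <- as.integer(parts[length(parts)])
    }
  }
  if (is.na(offset)) stop("readTck: header field 'file' missing or malformed")
  if (is.na(datatype) || datatype != "Float32LE")
    stop("readTck: header field 'datatype' must be Float32LE, got: ",
         datatype)
  nFloats <- (length(raw) - offset) %/% 4L
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric", n = nFloats,
                  size = 4L, endian = "little")
  pts <- matrix(vals[seq_len((length(vals) %/% 3L) * 3L)],
                ncol = 3L, byrow = TRUE)
  isInf <- is.infinite(pts[, 1])
  if (any(isInf)) pts <- pts[seq_len(which(isInf)[1] - 1L), , drop = FALSE]
  sep <- is.nan(pts[, 1])
  sl <- list()
  start <- 1L
  for (i in seq_len(nrow(pts))) {
    if (sep[i]) {
      if (i > start) sl[[length(sl) + 1L]] <- pts[start:(i - 1L), , drop = FALSE]
      start <- i + 1L
    }
  }
  if (start <= nrow(pts))
    sl[[length(sl) + 1L]] <- pts[start:nrow(pts), , drop = FALSE]
  if (!is.na(count) && count != length(sl))
    stop("readTck: header field 'count' (", count,
         ") disagrees with parsed streamlines (", length(sl), ")")
  if (is.null(grid)) grid <- imageGrid(c(1L, 1L, 1L), 1)
  if (is.null(name)) name <- basename(path)
  if (length(sl) == 0L)
    return(new("Tractogram", streamlines = list(), grid = grid, name = name))
  tractogram(sl, grid, name)
}

#' Write a Volume (or mask) as NIfTI-1
#'
#' The grid affine is stored in both qform and sform (code 2).
#' @param vol a [Volume-class] or [BinaryMask-class].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolumeNifti <- function(vol, path) {
  im <- RNifti::asNifti(vol@values)
  RNifti::pixdim(im) <- voxelSize(vol@grid)
  RNifti::qform(im) <- structure(vol@grid@affine, code = 2L)
  RNifti::sform(im) <- structure(vol@grid@affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI-1 file as a Volume
#'
#' @param path path to a NIfTI file.
#' @param mask logical: return a [BinaryMask-class] (values must already be
#'   0/1) instead of a [Volume-class].
#' @return a [Volume-class] or [BinaryMask-class].
#' @export
readVolumeNifti <- function(path, mask = FALSE) {
  im <- RNifti::readNifti(path)
  a <- unclass(RNifti::xform(im))[1:4, 1:4]
  d <- dim(im)
  if (length(d) != 3L)
    stop("readVolumeNifti: expected a 3-D volume, got ", length(d),
         " dimensions")
  g <- new("ImageGrid", dim = as.integer(d), affine = a)
  vals <- array(as.double(im), d)
  if (mask) binaryMask(g, vals) else volume(g, vals)
}

#' Construct a RunConfig
#'
#' @param nSubjects cohort size (default 20).
#' @param seedsPerVoxel tracking seeds per voxel (default 10).
#' @param densityFraction relative track-density threshold (default 0.25).
#' @param mpmFraction MPM retention fraction (default 0.50).
#' @param alpha significance level (default 0.05).
#' @param masterSeed master seed (default 42).
#' @param outDir output directory (default "ppntract-out").
#' @return a [RunConfig-class].
#' @export
runConfig <- function(nSubjects = 20L, seedsPerVoxel = 10L,
                      densityFraction = 0.25, mpmFraction = 0.50,
                      alpha = 0.05, masterSeed = 42L,
                      outDir = "ppntract-out") {
  new("RunConfig", nSubjects = as.integer(nSubjects),
      seedsPerVoxel = as.integer(seedsPerVoxel),
      densityFraction = densityFraction, mpmFraction = mpmFraction,
      alpha = alpha, masterSeed = as.integer(masterSeed), outDir = outDir)
}

.runConfigKeys <- c(n_subjects = "nSubjects",
                    seeds_per_voxel = "seedsPerVoxel",
                    density_fraction = "densityFraction",
                    mpm_fraction = "mpmFraction",
                    alpha = "alpha",
                    master_seed = "masterSeed",
                    out_dir = "outDir")

#' Load a run configuration from a flat key/value file
#'
#' The file holds one \code{key: value} pair per line (keys:
#' \code{n_subjects}, \code{seeds_per_voxel}, \code{density_fraction},
#' \code{mpm_fraction}, \code{alpha}, \code{master_seed}, \code{out_dir});
#' blank lines and lines starting with \code{#} are ignored. Absent keys
#' take the defaults of [runConfig()]. Out-of-range values raise a
#' validation error naming the offending key.
#'
#' @param path path to the config file.
#' @return a [RunConfig-class].
#' @seealso [saveRunConfig()]
#' @export
loadRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L)
      stop("loadRunConfig: malformed line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (!key %in% names(.runConfigKeys))
      stop("loadRunConfig: unknown key: ", key)
    slot <- .runConfigKeys[[key]]
    args[[slot]] <- if (slot == "outDir") val else as.numeric(val)
    if (slot != "outDir" && is.na(args[[slot]]))
      stop("loadRunConfig: non-numeric value for key: ", key)
  }
  # range checks naming the file key, before object construction
  checkRange <- function(slot, key, ok, what) {
    if (!is.null(args[[slot]]) && !ok(args[[slot]]))
      stop("loadRunConfig: key '", key, "' out of range: ", what,
           call. = FALSE)
  }
  checkRange("densityFraction", "density_fraction",
             function(x) x > 0 && x < 1, "must lie in (0, 1)")
  checkRange("mpmFraction", "mpm_fraction",
             function(x) x > 0 && x <= 1, "must lie in (0, 1]")
  checkRange("alpha", "alpha",
             function(x) x > 0 && x < 1, "must lie in (0, 1)")
  checkRange("nSubjects", "n_subjects",
             function(x) x >= 2, "cohort size must be >= 2")
  checkRange("seedsPerVoxel", "seeds_per_voxel",
             function(x) x >= 1, "must be >= 1")
  do.call(runConfig, args)
}

#' Save a run configuration as a flat key/value file
#'
#' @param config a [RunConfig-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
saveRunConfig <- function(config, path) {
  fmt <- function(x) {
    if (is.character(x)) x
    else if (x == round(x)) sprintf("%d", as.integer(x))
    else sprintf("%.6g", x)
  }
  lines <- vapply(names(.runConfigKeys), function(k)
    paste0(k, ": ", fmt(slot(config, .runConfigKeys[[k]]))), "")
  writeLines(lines, path)
  invisible(path)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: n =", object@nSubjects,
      "| seeds/voxel =", object@seedsPerVoxel,
      "| density cut =", object@densityFraction,
      "| MPM retention =", object@mpmFraction,
      "| alpha =", object@alpha,
      "| seed =", object@masterSeed, "\n")
})
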