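# Per-bundle NOS summaries, paired Wilcoxon signed-rank comparisons, and
# the end-to-end pipeline driver.

# distribution of 2W over all 2^n sign assignments of ranks (doubled
# midranks are integers); returns counts indexed by 2W = 0 .. n(n+1)
.signRankDist <- function(ranks2) {
  counts <- c(1, numeric(sum(ranks2)))
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Differences \code{d = x - y}; zero differences are dropped (the common
#' signed-rank convention); \code{|d|} is ranked with midranks for ties;
#' W is the sum of the ranks of positive differences. The two-sided p-value
#' is exact (full enumeration of all sign assignments) when the effective
#' sample size is at most \code{exactMax}, otherwise a tie-corrected normal
#' approximation with a 0.5 continuity correction is used; in both cases
#' p = min(1, 2 x one-sided tail).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @param exactMax largest effective n for exact enumeration (default 12).
#' @param pair optional character(2) labels of the compared conditions.
#' @return a [PairedTestResult-class].
#' @examples
#' r <- wilcoxonSignedRank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
#' r@statistic  # 15
#' r@pValue     # 0.0625
#' @export
wilcoxonSignedRank <- function(x, y, exactMax = 12L,
                               pair = c("x", "y")) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("wilcoxonSignedRank: x and y must be paired vectors of length >= 2")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("wilcoxonSignedRank: all differences are zero; test undefined")
  r <- rank(abs(d))  # midranks for ties
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    ranks2 <- as.integer(round(2 * r))
    counts <- .signRankDist(ranks2)
    tot <- 2^n
    w2 <- round(2 * W)
    pGe <- sum(counts[(w2 + 1):length(counts)]) / tot
    pLe <- sum(counts[1:(w2 + 1)]) / tot
    p <- min(1, 2 * min(pGe, pLe))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sig <- sqrt(sig2)
    if (W > mu) pOne <- pnorm((W - mu - 0.5) / sig, lower.tail = FALSE)
    else if (W < mu) pOne <- pnorm((W - mu + 0.5) / sig)
    else pOne <- 0.5
    p <- min(1, 2 * pOne)
    method <- "normal-approximation"
  }
  new("PairedTestResult", pair = pair, nTotal = length(x),
      nEffective = as.integer(n), statistic = W, pValue = p,
      method = method)
}

setMethod("show", "PairedTestResult", function(object) {
  cat("Wilcoxon signed rank: ", object@pair[1], " vs ", object@pair[2],
      " | W = ", object@statistic, ", n = ", object@nEffective,
      " (of ", object@nTotal, "), p = ", signif(object@pValue, 4),
      " [", object@method, "]\n", sep = "")
})

#' Per-bundle NOS mean and standard error
#'
#' @param table data.frame with columns subject, bundle, nos (one row per
#'   subject x bundle).
#' @return data.frame with columns bundle, n, mean, se (se = sample
#'   standard deviation / sqrt(n)).
#' @export
summarizeNos <- function(table) {
  stopifnot(all(c("subject", "bundle", "nos") %in% names(table)))
  sp <- split(table$nos, table$bundle)
  if (any(vapply(sp, length, 0L) < 2L))
    stop("summarizeNos: every bundle needs at least 2 subjects")
  out <- data.frame(bundle = names(sp),
                    n = vapply(sp, length, 0L),
                    mean = vapply(sp, mean, 0),
                    se = vapply(sp, function(v) sd(v) / sqrt(length(v)), 0))
  rownames(out) <- NULL
  out
}

.pallidalPairs <- list(
  c("L_GPi_ipsi", "L_GPe_ipsi"),
  c("R_GPi_ipsi", "R_GPe_ipsi"),
  c("L_GPi_ipsi", "L_GPi_contra"),
  c("R_GPi_ipsi", "R_GPi_contra"),
  c("L_GPi_ipsi", "R_GPi_ipsi"),
  c("L_GPe_ipsi", "R_GPe_ipsi"),
  c("L_GPi_contra", "R_GPi_contra"))

#' Run the standard pallidotegmental NOS comparisons
#'
#' Seven paired two-sided Wilcoxon signed-rank tests: GPi-ipsi vs GPe-ipsi
#' (per hemisphere), GPi-ipsi vs GPi-contra (per hemisphere), and left vs
#' right for GPi-ipsi, GPe-ipsi and GPi-contra. Significance is flagged at
#' \code{p < alpha}, uncorrected by default; \code{holm = TRUE} adds
#' Holm-adjusted p-values and flags on those instead.
#'
#' @param table NOS data.frame (columns subject, bundle, nos) containing
#'   all six bundles.
#' @param alpha significance level (default 0.05).
#' @param holm apply a Holm correction across the seven tests
#'   (default FALSE, matching uncorrected reporting).
#' @return data.frame with columns x, y, n_effective, W, p, (p_holm,)
#'   significant.
#' @export
runPallidalComparisons <- function(table, alpha = 0.05, holm = FALSE) {
  need <- unique(unlist(.pallidalPairs))
  miss <- setdiff(need, unique(table$bundle))
  if (length(miss) > 0L)
    stop("runPallidalComparisons: missing bundle(s): ",
         paste(miss, collapse = ", "))
  wide <- split(table, table$bundle)
  getv <- function(b) {
    t <- wide[[b]]
    t$nos[order(t$subject)]
  }
  rows <- lapply(.pallidalPairs, function(pr) {
    r <- wilcoxonSignedRank(getv(pr[1]), getv(pr[2]), pair = pr)
    data.frame(x = pr[1], y = pr[2], n_effective = r@nEffective,
               W = r@statistic, p = r@pValue, method = r@method)
  })
  out <- do.call(rbind, rows)
  if (holm) {
    out$p_holm <- stats::p.adjust(out$p, method = "holm")
    out$significant <- out$p_holm < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out
}

# concatenate ground-truth tractograms of a subject into one input per run
.combinedTract <- function(subject) {
  sl <- unlist(lapply(subject@tractograms, slot, "streamlines"),
               recursive = FALSE)
  new("Tractogram", streamlines = unname(sl), grid = subject@grid,
      name = "ground_truth_all")
}

#' Run the full phantom-cohort pipeline
#'
#' Generates the cohort, tracks from the four pallidal seed ROIs per
#' subject (or reuses the ground-truth tractograms), selects the six
#' pallidotegmental bundles, extracts NOS, builds per-subject PPN
#' connectivity clusters and group MPMs (cluster and territory), computes
#' percentage overlaps with the three functional territories per bundle,
#' and runs the seven paired comparisons. Writes deterministic CSV outputs
#' (\code{nos.csv}, \code{nos_summary.csv}, \code{comparisons.csv},
#' \code{overlap.csv}, \code{rejections.csv}) to \code{config@outDir} when
#' \code{write = TRUE}.
#'
#' @param config a [RunConfig-class].
#' @param phantom a [PhantomConfig-class]; its master seed is replaced by
#'   the run's master seed for end-to-end reproducibility.
#' @param params a [TrackingParams-class]; its \code{seedsPerVoxel} is
#'   replaced by \code{config@seedsPerVoxel}.
#' @param useGroundTruth select from the phantom's ground-truth
#'   tractograms instead of tracking (default FALSE).
#' @param write write CSV outputs to \code{config@outDir} (default TRUE).
#' @param writeMaps additionally write MPM NIfTI volumes (default FALSE).
#' @param verbose log one line per stage with kept/discarded counts.
#' @return invisible list with elements \code{nos}, \code{summary},
#'   \code{comparisons}, \code{overlap}, \code{rejections},
#'   \code{clusterMpms}, \code{territoryMpms}, \code{tractMpms}.
#' @export
runPipeline <- function(config = runConfig(), phantom = phantomConfig(),
                        params = trackingParams(),
                        useGroundTruth = FALSE, write = TRUE,
                        writeMaps = FALSE, verbose = FALSE) {
  set.seed(config@masterSeed)
  phantomSeed <- sample.int(.Machine$integer.max - 1L, 1)
  trackSeeds <- sample.int(.Machine$integer.max - 1L, config@nSubjects)
  phantom@masterSeed <- phantomSeed
  params@seedsPerVoxel <- config@seedsPerVoxel
  log1 <- function(...) if (verbose) message(sprintf(...))

  log1("generating cohort: n = %d", config@nSubjects)
  cohort <- generateCohort(phantom, config@nSubjects)
  tplGrid <- phantom@grid

  bundleNames <- c("L_GPi_ipsi", "R_GPi_ipsi", "L_GPe_ipsi", "R_GPe_ipsi",
                   "L_GPi_contra", "R_GPi_contra")
  seedOf <- c(L_GPi_ipsi = "GPi_L", R_GPi_ipsi = "GPi_R",
              L_GPe_ipsi = "GPe_L", R_GPe_ipsi = "GPe_R",
              L_GPi_contra = "GPi_L", R_GPi_contra = "GPi_R")

  nosRows <- list(); rejRows <- list()
  clusters <- lapply(bundleNames, function(b) list())
  names(clusters) <- bundleNames
  densities <- lapply(bundleNames, function(b) list())
  names(densities) <- bundleNames
  transforms <- list()
  terrMasks <- list()

  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    specs <- buildPallidotegmentalSpecs(sub@masks)
    set.seed(trackSeeds[i])
    inputs <- list()
    if (useGroundTruth) {
      all <- .combinedTract(sub)
      for (b in bundleNames) inputs[[b]] <- all
    } else {
      for (sr in unique(seedOf)) {
        tr <- trackFromSeedMask(sub@masks[[sr]], sub@field, params,
                                name = paste0(sub@id, "_", sr))
        for (b in bundleNames[seedOf == sr]) inputs[[b]] <- tr
      }
    }
    for (b in bundleNames) {
      res <- selectBundle(inputs[[b]], specs[[b]])
      log1("%s %s: NOS %d / %d (exclude %d, include %d)", sub@id, b,
           res@nos, res@nInput, res@rejectedExclude, res@rejectedInclude)
      nosRows[[length(nosRows) + 1L]] <-
        data.frame(subject = sub@id, bundle = b, nos = res@nos)
      rejRows[[length(rejRows) + 1L]] <-
        data.frame(subject = sub@id, bundle = b, nos = res@nos,
                   rejected_include = res@rejectedInclude,
                   rejected_exclude = res@rejectedExclude,
                   rejected_seed = res@rejectedSeed,
                   n_input = res@nInput)
      roi <- sub@masks[[seedOf[b]]]
      clusters[[b]][[sub@id]] <- subjectConnectivityCluster(
        res@tractogram, roi, sub@transform, tplGrid,
        config@densityFraction)
      d <- trackDensityMap(res@tractogram, sub@grid)
      densities[[b]][[sub@id]] <- d
    }
    transforms[[sub@id]] <- sub@transform
    for (seg in c("GPi_L", "GPi_R", "GPe_L", "GPe_R"))
      for (tn in c("limbic", "associative", "sensorimotor")) {
        key <- paste(seg, tn, sep = "_")
        terrMasks[[key]][[sub@id]] <-
          applyTransform(sub@masks[[key]], sub@transform, tplGrid)
      }
  }

  nos <- do.call(rbind, nosRows)
  rejections <- do.call(rbind, rejRows)
  summary <- summarizeNos(nos)
  comparisons <- runPallidalComparisons(nos, alpha = config@alpha)

  clusterMpms <- lapply(clusters, maximumProbabilityMap,
                        retentionFraction = config@mpmFraction)
  territoryMpms <- lapply(terrMasks, maximumProbabilityMap,
                          retentionFraction = config@mpmFraction)
  tractMpms <- lapply(bundleNames, function(b)
    tractMpm(densities[[b]], transforms[names(densities[[b]])], tplGrid,
             config@mpmFraction))
  names(tractMpms) <- bundleNames

  ovRows <- list()
  for (b in bundleNames) {
    seg <- seedOf[b]
    hemi <- sub("GP[ie]_", "", seg)
    for (tn in c("limbic", "associative", "sensorimotor")) {
      terr <- territoryMpms[[paste(seg, tn, sep = "_")]]
      pct <- if (maskVolume(mpmMask(terr)) == 0) NA_real_
      else percentageOverlap(mpmMask(clusterMpms[[b]]), mpmMask(terr))
      ovRows[[length(ovRows) + 1L]] <-
        data.frame(bundle = b, hemisphere = hemi, territory = tn,
                   percent_overlap = pct)
    }
  }
  overlap <- do.call(rbind, ovRows)

  if (write) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, f)
      write.csv(x, file.path(config@outDir, f), row.names = FALSE)
    wcsv(nos, "nos.csv")
    wcsv(summary, "nos_summary.csv")
    wcsv(comparisons, "comparisons.csv")
    wcsv(overlap, "overlap.csv")
    wcsv(rejections, "rejections.csv")
    if (writeMaps) {
      for (b in bundleNames) {
        writeVolumeNifti(clusterMpms[[b]],
                         file.path(config@outDir,
                                   paste0("cluster_mpm_", b, ".nii.gz")))
        writeVolumeNifti(tractMpms[[b]],
                         file.path(config@outDir,
                                   paste0("tract_mpm_", b, ".nii.gz")))
      }
    }
  }

  invisible(list(nos = nos, summary = summary, comparisons = comparisons,
                 overlap = overlap, rejections = rejections,
                 clusterMpms = clusterMpms, territoryMpms = territoryMpms,
                 tractMpms = tractMpms))
}
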