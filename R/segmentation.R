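#' Liver-referenced segmentation threshold
#'
#' The adaptive whole-body threshold is
#' \deqn{(4.3 / SUVmean_{liver}) \times (SUVmean_{liver} + SUVsd_{liver})}
#' so a noise-free liver (sd = 0) yields exactly the reference constant
#' 4.3 SUV, and the threshold grows with liver noise.
#'
#' @param liverSuvMean liver mean SUV (> 0).
#' @param liverSuvSd liver SUV standard deviation (>= 0).
#' @param referenceConstant fixed reference constant (4.3 SUV).
#' @return the threshold (SUV).
#' @examples
#' computeThreshold(5, 1)   # 5.16
#' computeThreshold(2, 0.5) # 5.375
#' @export
computeThreshold <- function(liverSuvMean, liverSuvSd,
                             referenceConstant = 4.3) {
  if (!is.finite(liverSuvMean) || liverSuvMean <= 0)
    stop("liverSuvMean must be > 0")
  if (!is.finite(liverSuvSd) || liverSuvSd < 0)
    stop("liverSuvSd must be >= 0")
  (referenceConstant / liverSuvMean) * (liverSuvMean + liverSuvSd)
}

#' Liver reference statistics for a scan
#'
#' Computes liver SUVmean and SUVsd over the liver mask (or an explicit
#' reference ROI such as a [sphericalRoi()]) and derives the segmentation
#' threshold. The standard deviation uses the population (divide-by-n)
#' convention by default; the sample convention is available because the
#' reference-region definition is a configuration choice, not a fixed
#' property of the method.
#'
#' @param volume a [PetVolume-class].
#' @param masks an [OrganMaskSet-class] containing a \code{liver} label.
#' @param sdConvention \code{"population"} (default) or \code{"sample"}.
#' @param roiMask optional logical array selecting the reference voxels
#'   instead of the whole liver label.
#' @param referenceConstant see [computeThreshold()].
#' @return a [ReferenceStats-class].
#' @export
liverReferenceStats <- function(volume, masks,
                                sdConvention = c("population", "sample"),
                                roiMask = NULL, referenceConstant = 4.3) {
  sdConvention <- match.arg(sdConvention)
  if (is.null(roiMask)) {
    stopIfNot3dCongruent(volume, masks)
    if (!"liver" %in% names(masks@labelMap))
      stop("no liver label in the organ mask set")
    roiMask <- masks@labels == masks@labelMap[["liver"]]
  }
  vals <- volume@values[roiMask]
  if (!length(vals)) stop("liver reference mask is empty")
  m <- mean(vals)
  s <- if (sdConvention == "population") popSd(vals) else stats::sd(vals)
  if (length(vals) == 1L) s <- 0
  new("ReferenceStats", liverSuvMean = m, liverSuvSd = s,
      threshold = computeThreshold(m, s, referenceConstant),
      referenceConstant = referenceConstant)
}

#' Detect supra-threshold foci
#'
#' Connected components (26-connectivity) of the strict supra-threshold
#' set \{voxel : SUV > threshold\}. Each focus carries its voxel set, its
#' SUVmax, and the argmax voxel as seed; components smaller than
#' \code{minVoxels} are dropped. Foci are ordered (and numbered) by their
#' smallest linear voxel index, so detection is deterministic.
#'
#' @param volume a [PetVolume-class].
#' @param threshold segmentation threshold (SUV, > 0).
#' @param minVoxels minimum component size retained (default 1).
#' @return list of foci; each a list with \code{id}, \code{voxels}
#'   (integer matrix), \code{suvMax}, \code{seed} (length-3 index).
#' @export
detectFoci <- function(volume, threshold, minVoxels = 1L) {
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be > 0")
  mask <- volume@values > threshold
  labels <- labelComponents(mask)
  nlab <- max(labels)
  if (nlab == 0L) return(list())
  foci <- vector("list", nlab)
  keep <- logical(nlab)
  vox <- which(labels > 0L)
  byLab <- split(vox, labels[vox])
  for (lb in seq_len(nlab)) {
    idx <- byLab[[as.character(lb)]]
    if (length(idx) < minVoxels) next
    vals <- volume@values[idx]
    seedIdx <- idx[which.max(vals)]
    foci[[lb]] <- list(id = lb,
                       voxels = linearToCoords(idx, dim(volume@values)),
                       suvMax = max(vals),
                       seed = as.integer(linearToCoords(seedIdx,
                                                        dim(volume@values))))
    keep[lb] <- TRUE
  }
  foci <- foci[keep]
  for (i in seq_along(foci)) foci[[i]]$id <- i
  foci
}

#' Review adjustments for the semi-automatic step
#'
#' Stand-in for the physician review of the preliminary segmentation:
#' focus ids to drop regardless of organ overlap, and seed coordinates to
#' force back in (the liver-metastasis re-segmentation path).
#'
#' @param excludeFoci integer focus ids to remove.
#' @param includeRegions integer matrix (rows = i, j, k grid indices) of
#'   seeds to re-insert as foci even inside organ masks. Seeds should sit
#'   on the lesion's hottest voxel, since the 50 percent rule is anchored
#'   at the seed's SUV.
#' @return a list with class \code{reviewAdjustments}.
#' @export
reviewAdjustments <- function(excludeFoci = integer(),
                              includeRegions = NULL) {
  if (!is.null(includeRegions)) {
    includeRegions <- matrix(as.integer(includeRegions), ncol = 3L)
  }
  structure(list(excludeFoci = as.integer(excludeFoci),
                 includeRegions = includeRegions),
            class = "reviewAdjustments")
}

#' Remove physiological-uptake foci
#'
#' A focus is removed when the fraction of its voxels lying inside the
#' organ masks (liver, spleen, kidneys) strictly exceeds
#' \code{overlapFrac}; metastases merely abutting an organ survive. Foci
#' listed in the adjustments' \code{excludeFoci} are removed regardless;
#' \code{includeRegions} seeds are re-inserted as single-voxel foci even
#' inside organ masks.
#'
#' @param foci list of foci from [detectFoci()].
#' @param masks an [OrganMaskSet-class].
#' @param adjustments a [reviewAdjustments()] object, or NULL.
#' @param overlapFrac organ-overlap removal fraction (default 0.5).
#' @param volume the [PetVolume-class]; needed to give re-inserted seeds
#'   their SUV (may be omitted when there are no include regions).
#' @return the retained foci, ids renumbered consecutively.
#' @export
excludePhysiological <- function(foci, masks, adjustments = NULL,
                                 overlapFrac = 0.5, volume = NULL) {
  dims <- dim(masks@labels)
  keep <- vapply(foci, function(f) {
    inOrgan <- masks@labels[f$voxels] > 0L
    mean(inOrgan) <= overlapFrac
  }, logical(1))
  if (!is.null(adjustments) && length(adjustments$excludeFoci))
    keep[vapply(foci, `[[`, integer(1), "id") %in%
           adjustments$excludeFoci] <- FALSE
  out <- foci[keep]
  if (!is.null(adjustments) && !is.null(adjustments$includeRegions)) {
    ir <- adjustments$includeRegions
    for (r in seq_len(nrow(ir))) {
      seed <- ir[r, ]
      if (any(seed < 1L) || any(seed > dims))
        stop("include-region seed outside the grid")
      suv <- if (is.null(volume)) NA_real_ else
        volume@values[seed[1L], seed[2L], seed[3L]]
      out[[length(out) + 1L]] <- list(
        id = NA_integer_, voxels = matrix(seed, 1L, 3L),
        suvMax = suv, seed = as.integer(seed))
    }
  }
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Refine one focus by the 50 percent-of-local-SUVmax rule
#'
#' The local SUVmax is the maximum SUV over the focus; the refined lesion
#' is the 26-connected component of \{voxel : SUV >= 0.5 x local SUVmax\}
#' containing the focus' hottest voxel. The refinement may extend beyond
#' the initial supra-threshold focus. Lesion metrics (SUVmax, SUVmean,
#' volume in ml, per-lesion TLQ = volume / SUVmean) are filled in.
#'
#' @param volume a [PetVolume-class].
#' @param focus one focus from [detectFoci()] (or a re-inserted seed).
#' @param lesionId id to assign (defaults to the focus id).
#' @return a [LesionSegment-class].
#' @export
refineLesion <- function(volume, focus, lesionId = focus$id) {
  dims <- dim(volume@values)
  idx <- coordsToLinear(focus$voxels, dims)
  if (!length(idx)) stop("focus is empty")
  vals <- volume@values[idx]
  localMax <- max(vals)
  seedIdx <- idx[which.max(vals)]
  mask <- volume@values >= 0.5 * localMax
  comp <- componentContaining(mask, seedIdx)
  newLesionSegment(volume, comp, lesionId)
}

# Build a LesionSegment from sorted linear voxel indices.
newLesionSegment <- function(volume, linIdx, lesionId) {
  vals <- volume@values[linIdx]
  vml <- length(linIdx) * voxelVolumeMm3(volume@spacing) / 1000
  new("LesionSegment",
      lesionId = as.integer(if (is.na(lesionId)) 0L else lesionId),
      voxels = linearToCoords(linIdx, dim(volume@values)),
      suvMax = max(vals), suvMean = mean(vals), volumeMl = vml,
      tlqLesion = vml / mean(vals))
}

#' Segment all metastases in a scan
#'
#' The full semi-automatic chain: liver-referenced threshold, detection of
#' supra-threshold foci, physiological-organ exclusion with review
#' adjustments, 50 percent-of-local-SUVmax refinement, and deduplication
#' of refinements whose isocontours merged (identical voxel sets collapse;
#' overlapping sets merge by union so no volume is double-counted).
#' Lesions are returned sorted by descending volume with a stable
#' tie-break on the originating focus index.
#'
#' @inheritParams liverReferenceStats
#' @inheritParams excludePhysiological
#' @inheritParams detectFoci
#' @param threshold optional fixed threshold (SUV); when supplied the
#'   liver reference step is skipped.
#' @return list with elements \code{lesions} (list of
#'   [LesionSegment-class]), \code{referenceStats} and \code{threshold}.
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(seed = 3, psfFwhmMm = 0,
#'                                          noiseSd = 0))
#' seg <- segmentScan(ph@volume, ph@organMasks)
#' length(seg$lesions)
#' @export
segmentScan <- function(volume, masks, adjustments = NULL, minVoxels = 1L,
                        overlapFrac = 0.5,
                        sdConvention = c("population", "sample"),
                        roiMask = NULL, threshold = NULL) {
  sdConvention <- match.arg(sdConvention)
  stopIfNot3dCongruent(volume, masks)
  refStats <- NULL
  if (is.null(threshold)) {
    refStats <- liverReferenceStats(volume, masks, sdConvention, roiMask)
    threshold <- refStats@threshold
  }
  foci <- detectFoci(volume, threshold, minVoxels)
  foci <- excludePhysiological(foci, masks, adjustments, overlapFrac,
                               volume = volume)
  if (!length(foci))
    return(list(lesions = list(), referenceStats = refStats,
                threshold = threshold))

  dims <- dim(volume@values)
  refined <- lapply(foci, function(f)
    sort(coordsToLinear(lesionVoxels(refineLesion(volume, f)), dims)))

  # merge refinements that share voxels (union-find over overlap graph)
  nset <- length(refined)
  parent <- seq_len(nset)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nset - 1L)) for (j in (i + 1L):nset) {
    if (findRoot(i) != findRoot(j) &&
        length(intersect(refined[[i]], refined[[j]])))
      parent[findRoot(j)] <- findRoot(i)
  }
  roots <- vapply(seq_len(nset), findRoot, integer(1))
  groups <- split(seq_len(nset), roots)

  lesions <- lapply(groups, function(g) {
    linIdx <- sort(unique(unlist(refined[g])))
    seg <- newLesionSegment(volume, linIdx, lesionId = min(g))
    attr(seg, "seedIndex") <- min(g)
    seg
  })
  vol <- vapply(lesions, volumeMl, numeric(1))
  seedIx <- vapply(lesions, function(l) attr(l, "seedIndex"), numeric(1))
  lesions <- lesions[order(-vol, seedIx)]
  for (i in seq_along(lesions)) lesions[[i]]@lesionId <- i
  names(lesions) <- NULL
  list(lesions = lesions, referenceStats = refStats, threshold = threshold)
}

#' Per-lesion table for export
#'
#' @param lesions list of [LesionSegment-class].
#' @param scanId,timepoint scan identity columns.
#' @return data.frame with one row per lesion.
#' @export
lesionTable <- function(lesions, scanId = "scan", timepoint = "baseline") {
  if (!length(lesions))
    return(data.frame(scan_id = character(), timepoint = character(),
                      lesion_id = integer(), n_voxels = integer(),
                      suv_max = numeric(), suv_mean = numeric(),
                      volume_ml = numeric(), tlq_lesion = numeric()))
  data.frame(
    scan_id = scanId, timepoint = timepoint,
    lesion_id = vapply(lesions, function(l) l@lesionId, integer(1)),
    n_voxels = vapply(lesions, function(l) nrow(l@voxels), integer(1)),
    suv_max = vapply(lesions, suvMax, numeric(1)),
    suv_mean = vapply(lesions, suvMean, numeric(1)),
    volume_ml = vapply(lesions, volumeMl, numeric(1)),
    tlq_lesion = vapply(lesions, tlqLesion, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Lesion label volume
#'
#' @param lesions list of [LesionSegment-class].
#' @param volume the segmented [PetVolume-class] (for the grid shape).
#' @return integer array labelling each lesion's voxels by its id.
#' @export
lesionLabelVolume <- function(lesions, volume) {
  lab <- array(0L, dim(volume@values))
  for (l in lesions) lab[l@voxels] <- l@lesionId
  lab
}
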