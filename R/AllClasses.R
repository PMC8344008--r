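#' @import methods
NULL

#' SUV-calibrated 3-D PET volume
#'
#' Container for a whole-body PET scan expressed in standardized uptake
#' values (SUV). The grid is a plain 3-D array; world coordinates are
#' voxel-center based, 0-based, and derived from the voxel spacing only
#' (no oblique affine is carried).
#'
#' @slot values 3-D numeric array of SUV (dimensionless, finite, >= 0).
#' @slot spacing numeric length-3 voxel spacing in mm (all > 0).
#' @slot scanId scan identifier.
#' @slot timepoint one of \code{"baseline"} or \code{"interim"}.
#'
#' @seealso [petVolume()], [readPetVolume()], [segmentScan()]
#' @export
setClass("PetVolume",
  representation(values = "array", spacing = "numeric",
                 scanId = "character", timepoint = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3-D array")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "all SUV values must be finite")
    else if (any(object@values < 0))
      msg <- c(msg, "all SUV values must be >= 0")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@timepoint) != 1L ||
        !object@timepoint %in% c("baseline", "interim"))
      msg <- c(msg, "timepoint must be 'baseline' or 'interim'")
    if (length(msg)) msg else TRUE
  })

#' Organ label masks congruent with a PET volume
#'
#' Integer label volume marking physiological-uptake organs (liver, spleen,
#' kidneys) whose supra-threshold foci are removed from the metastasis
#' segmentation, plus the map from organ name to label.
#'
#' @slot labels 3-D integer array, 0 = unlabelled.
#' @slot labelMap named integer vector, organ name -> positive label.
#'
#' @seealso [organMaskSet()], [excludePhysiological()]
#' @export
setClass("OrganMaskSet",
  representation(labels = "array", labelMap = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3-D array")
    if (any(object@labels < 0)) msg <- c(msg, "labels must be nonnegative")
    if (length(object@labelMap) &&
        (is.null(names(object@labelMap)) || any(object@labelMap <= 0)))
      msg <- c(msg, "labelMap must be a named vector of positive labels")
    if (length(msg)) msg else TRUE
  })

#' Liver reference statistics and the derived segmentation threshold
#'
#' The adaptive whole-body segmentation threshold is liver-referenced:
#' threshold = (4.3 / liver SUVmean) x (liver SUVmean + liver SUVsd).
#'
#' @slot liverSuvMean liver mean SUV over the reference mask.
#' @slot liverSuvSd liver SUV standard deviation (population convention).
#' @slot threshold derived segmentation threshold (SUV).
#' @slot referenceConstant the fixed reference constant, 4.3 SUV.
#'
#' @seealso [liverReferenceStats()], [computeThreshold()]
#' @export
setClass("ReferenceStats",
  representation(liverSuvMean = "numeric", liverSuvSd = "numeric",
                 threshold = "numeric", referenceConstant = "numeric"),
  prototype(referenceConstant = 4.3),
  validity = function(object) {
    msg <- character()
    if (object@liverSuvMean <= 0) msg <- c(msg, "liverSuvMean must be > 0")
    if (object@liverSuvSd < 0) msg <- c(msg, "liverSuvSd must be >= 0")
    if (object@threshold <= 0) msg <- c(msg, "threshold must be > 0")
    if (length(msg)) msg else TRUE
  })

#' One segmented metastasis
#'
#' A single lesion after 50 percent-of-local-SUVmax isocontour refinement:
#' its voxel set (26-connected), SUV statistics, volume in ml, and the
#' per-lesion total lesion quotient TLQ = volume / SUVmean.
#'
#' @slot lesionId integer lesion identifier within the scan.
#' @slot voxels integer matrix, one row per voxel (i, j, k grid indices).
#' @slot suvMax maximum SUV over the voxel set.
#' @slot suvMean mean SUV over the voxel set.
#' @slot volumeMl lesion volume in ml (= nrow(voxels) x voxel volume / 1000).
#' @slot tlqLesion volumeMl / suvMean.
#'
#' @seealso [refineLesion()], [aggregateScan()]
#' @export
setClass("LesionSegment",
  representation(lesionId = "integer", voxels = "matrix",
                 suvMax = "numeric", suvMean = "numeric",
                 volumeMl = "numeric", tlqLesion = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@voxels) < 1L) msg <- c(msg, "voxel set must be nonempty")
    if (ncol(object@voxels) != 3L) msg <- c(msg, "voxels must have 3 columns")
    if (object@suvMean > object@suvMax + 1e-12)
      msg <- c(msg, "suvMean must not exceed suvMax")
    if (length(msg)) msg else TRUE
  })

#' Per-scan aggregate metrics
#'
#' PSMA-TV (total tumor volume, ml), summed TLQ (ml), mean SUVmax
#' (unweighted over lesions; NA when no lesion) and the lesion count.
#'
#' @slot scanId scan identifier.
#' @slot timepoint \code{"baseline"} or \code{"interim"}.
#' @slot psmaTv total tumor volume in ml.
#' @slot tlqSum summed per-lesion TLQ in ml.
#' @slot meanSuvMax unweighted mean of lesion SUVmax; NA if no lesions.
#' @slot nLesions lesion count.
#'
#' @seealso [aggregateScan()], [classifyTvResponse()]
#' @export
setClass("ScanMetrics",
  representation(scanId = "character", timepoint = "character",
                 psmaTv = "numeric", tlqSum = "numeric",
                 meanSuvMax = "numeric", nLesions = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@psmaTv < 0) msg <- c(msg, "psmaTv must be >= 0")
    if (object@tlqSum < 0) msg <- c(msg, "tlqSum must be >= 0")
    if (object@nLesions == 0L &&
        (object@psmaTv != 0 || object@tlqSum != 0 || !is.na(object@meanSuvMax)))
      msg <- c(msg, "zero lesions implies zero volumes and NA meanSuvMax")
    if (length(msg)) msg else TRUE
  })

#' Specification of a synthetic PET phantom
#'
#' Describes a whole-body-like digital phantom: uniform background uptake,
#' ellipsoidal organs with per-voxel Gaussian uptake, spherical lesions of
#' known peak SUV, Gaussian point-spread blur and additive noise.
#'
#' @slot gridShape integer length-3 grid dimensions (each >= 8).
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot backgroundSuv uniform background SUV.
#' @slot organs data.frame: name, cx, cy, cz (mm), rx, ry, rz (mm),
#'   meanSuv, sdSuv.
#' @slot lesions data.frame: cx, cy, cz (mm), radius (mm), peakSuv.
#' @slot psfFwhmMm Gaussian PSF full-width-half-maximum in mm (0 = none).
#' @slot noiseSd additive Gaussian noise SD in SUV (clipped at 0).
#' @slot seed integer RNG seed.
#'
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 backgroundSuv = "numeric", organs = "data.frame",
                 lesions = "data.frame", psfFwhmMm = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
      msg <- c(msg, "gridShape must be 3 integers, each >= 8")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@psfFwhmMm < 0) msg <- c(msg, "psfFwhmMm must be >= 0")
    if (nrow(object@organs)) {
      ok <- object@organs$name %in%
        c("liver", "spleen", "kidney_left", "kidney_right")
      if (!all(ok)) msg <- c(msg, "unknown organ name")
      if (any(object@organs[, c("rx", "ry", "rz")] <= 0))
        msg <- c(msg, "organ radii must be > 0")
    }
    if (nrow(object@lesions)) {
      if (any(object@lesions$radius <= 0))
        msg <- c(msg, "lesion radii must be > 0")
      if (any(object@lesions$peakSuv <= object@backgroundSuv))
        msg <- c(msg, "lesion peakSuv must exceed backgroundSuv")
    }
    if (length(msg)) msg else TRUE
  })

#' Specification of a simulated therapy cohort
#'
#' Parameters of the cohort simulator: cohort size, log-hazard coefficients
#' for log baseline tumor volume and for true volumetric response, the
#' low-PSMA-expression fraction (whose observed volume decline is decoupled
#' from their hazard), the baseline tumor-volume log-normal and the
#' administrative censoring rate.
#'
#' @slot nPatients cohort size (>= 2).
#' @slot betaLogTv log-hazard per unit log baseline PSMA-TV.
#' @slot betaResponse log-hazard for true volumetric response (< 0 benefits).
#' @slot fracLowExpression proportion with baseline meanSUVmax <= 14.3.
#' @slot tvMedianMl median of the baseline PSMA-TV log-normal (ml).
#' @slot tvIqrMl interquartile range of baseline PSMA-TV (ml).
#' @slot censoringRate target administrative censoring proportion in [0, 1).
#' @slot seed integer RNG seed.
#'
#' @seealso [cohortSimSpec()], [simulateCohort()]
#' @export
setClass("CohortSimSpec",
  representation(nPatients = "integer", betaLogTv = "numeric",
                 betaResponse = "numeric", fracLowExpression = "numeric",
                 tvMedianMl = "numeric", tvIqrMl = "numeric",
                 censoringRate = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nPatients < 2L) msg <- c(msg, "nPatients must be >= 2")
    if (object@fracLowExpression < 0 || object@fracLowExpression > 1)
      msg <- c(msg, "fracLowExpression must be in [0, 1]")
    if (object@censoringRate < 0 || object@censoringRate >= 1)
      msg <- c(msg, "censoringRate must be in [0, 1)")
    if (object@tvMedianMl <= 0 || object@tvIqrMl <= 0)
      msg <- c(msg, "baseline TV distribution parameters must be > 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PetVolume", function(object) {
  d <- dim(object@values)
  cat("PetVolume '", object@scanId, "' (", object@timepoint, ")\n",
      "  grid ", paste(d, collapse = " x "),
      ", spacing ", paste(format(object@spacing), collapse = " x "), " mm\n",
      "  SUV range [", format(min(object@values), digits = 4), ", ",
      format(max(object@values), digits = 4), "]\n", sep = "")
})

setMethod("show", "OrganMaskSet", function(object) {
  cat("OrganMaskSet:", paste(names(object@labelMap), collapse = ", "), "\n")
})

setMethod("show", "ReferenceStats", function(object) {
  cat("ReferenceStats: liver SUVmean ", format(object@liverSuvMean, digits = 4),
      ", SUVsd ", format(object@liverSuvSd, digits = 4),
      " -> threshold ", format(object@threshold, digits = 4), "\n", sep = "")
})

setMethod("show", "LesionSegment", function(object) {
  cat("LesionSegment #", object@lesionId, ": ", nrow(object@voxels),
      " voxels, ", format(object@volumeMl, digits = 4), " ml, SUVmax ",
      format(object@suvMax, digits = 4), ", TLQ ",
      format(object@tlqLesion, digits = 4), "\n", sep = "")
})

setMethod("show", "ScanMetrics", function(object) {
  cat("ScanMetrics '", object@scanId, "' (", object@timepoint, "): ",
      object@nLesions, " lesions, PSMA-TV ",
      format(object@psmaTv, digits = 5), " ml, TLQ ",
      format(object@tlqSum, digits = 5), ", meanSUVmax ",
      format(object@meanSuvMax, digits = 4), "\n", sep = "")
})
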