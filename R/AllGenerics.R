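#' @rdname PetVolume-class
#' @param object a \code{PetVolume}, \code{ScanMetrics} or related object
#' @export
setGeneric("suvValues", function(object) standardGeneric("suvValues"))

#' @rdname PetVolume-class
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname PetVolume-class
#' @export
setGeneric("scanId", function(object) standardGeneric("scanId"))

#' @rdname PetVolume-class
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))

#' @rdname ScanMetrics-class
#' @param object a \code{ScanMetrics}
#' @export
setGeneric("psmaTv", function(object) standardGeneric("psmaTv"))

#' @rdname ScanMetrics-class
#' @export
setGeneric("tlqSum", function(object) standardGeneric("tlqSum"))

#' @rdname ScanMetrics-class
#' @export
setGeneric("meanSuvMax", function(object) standardGeneric("meanSuvMax"))

#' @rdname ScanMetrics-class
#' @export
setGeneric("nLesions", function(object) standardGeneric("nLesions"))

#' @rdname LesionSegment-class
#' @param object a \code{LesionSegment}
#' @export
setGeneric("lesionVoxels", function(object) standardGeneric("lesionVoxels"))

#' @rdname LesionSegment-class
#' @export
setGeneric("volumeMl", function(object) standardGeneric("volumeMl"))

#' @rdname LesionSegment-class
#' @export
setGeneric("suvMax", function(object) standardGeneric("suvMax"))

#' @rdname LesionSegment-class
#' @export
setGeneric("suvMean", function(object) standardGeneric("suvMean"))

#' @rdname LesionSegment-class
#' @export
setGeneric("tlqLesion", function(object) standardGeneric("tlqLesion"))

#' @rdname ReferenceStats-class
#' @param object a \code{ReferenceStats}
#' @export
setGeneric("segThreshold", function(object) standardGeneric("segThreshold"))

setMethod("suvValues", "PetVolume", function(object) object@values)
setMethod("voxelSpacing", "PetVolume", function(object) object@spacing)
setMethod("scanId", "PetVolume", function(object) object@scanId)
setMethod("timepoint", "PetVolume", function(object) object@timepoint)
setMethod("scanId", "ScanMetrics", function(object) object@scanId)
setMethod("timepoint", "ScanMetrics", function(object) object@timepoint)
setMethod("psmaTv", "ScanMetrics", function(object) object@psmaTv)
setMethod("tlqSum", "ScanMetrics", function(object) object@tlqSum)
setMethod("meanSuvMax", "ScanMetrics", function(object) object@meanSuvMax)
setMethod("nLesions", "ScanMetrics", function(object) object@nLesions)
setMethod("lesionVoxels", "LesionSegment", function(object) object@voxels)
setMethod("volumeMl", "LesionSegment", function(object) object@volumeMl)
setMethod("suvMax", "LesionSegment", function(object) object@suvMax)
setMethod("suvMean", "LesionSegment", function(object) object@suvMean)
setMethod("tlqLesion", "LesionSegment", function(object) object@tlqLesion)
setMethod("segThreshold", "ReferenceStats", function(object) object@threshold)
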