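#' Construct a PetVolume
#'
#' @param values 3-D numeric array of SUV.
#' @param spacing voxel spacing in mm (length 3, or a scalar recycled).
#' @param scanId scan identifier.
#' @param timepoint \code{"baseline"} or \code{"interim"}.
#' @return a [PetVolume-class] object.
#' @examples
#' v <- petVolume(array(1, c(8, 8, 8)), spacing = 2, scanId = "demo")
#' v
#' @export
petVolume <- function(values, spacing = c(2, 2, 2), scanId = "scan",
                      timepoint = c("baseline", "interim")) {
  timepoint <- match.arg(timepoint)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PetVolume", values = values, spacing = as.numeric(spacing),
      scanId = as.character(scanId), timepoint = timepoint)
}

#' Construct an OrganMaskSet
#'
#' @param labels 3-D integer array of organ labels (0 = none).
#' @param labelMap named integer vector, organ name -> label. Defaults to
#'   the labels present in the array, named \code{organ<label>}.
#' @return an [OrganMaskSet-class] object.
#' @export
organMaskSet <- function(labels, labelMap = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(labelMap)) {
    u <- sort(unique(labels[labels > 0L]))
    labelMap <- stats::setNames(as.integer(u), paste0("organ", u))
  }
  new("OrganMaskSet", labels = labels,
      labelMap = stats::setNames(as.integer(labelMap), names(labelMap)))
}

#' Read a PET volume from NIfTI
#'
#' Reads an SUV-calibrated NIfTI volume; voxel spacing is taken from the
#' image's pixdim.
#'
#' @param path path to a .nii or .nii.gz file.
#' @inheritParams petVolume
#' @return a [PetVolume-class].
#' @export
readPetVolume <- function(path, scanId = basename(path),
                          timepoint = c("baseline", "interim")) {
  timepoint <- match.arg(timepoint)
  img <- RNifti::readNifti(path)
  petVolume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3],
            scanId = scanId, timepoint = timepoint)
}

#' Write a PET volume (or label volume) to NIfTI
#'
#' @param volume a [PetVolume-class], or a plain 3-D array (labels).
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel spacing in mm; taken from the volume when omitted.
#' @return the path, invisibly.
#' @export
writePetVolume <- function(volume, path, spacing = NULL) {
  if (is(volume, "PetVolume")) {
    arr <- volume@values
    if (is.null(spacing)) spacing <- volume@spacing
  } else {
    arr <- volume
    if (is.null(spacing)) spacing <- c(1, 1, 1)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an organ-label volume from NIfTI
#'
#' @param path path to an integer label NIfTI.
#' @param labelMap named integer vector mapping organ names to labels;
#'   defaults to the labels found in the file.
#' @return an [OrganMaskSet-class].
#' @export
readOrganMasks <- function(path, labelMap = NULL) {
  img <- RNifti::readNifti(path)
  organMaskSet(array(as.integer(round(img)), dim = dim(img)), labelMap)
}

#' Spherical reference ROI at a world coordinate
#'
#' Utility to place a spherical volume of interest (e.g. a liver reference
#' region) of a given radius at a given voxel-center world coordinate.
#' Voxel centers are at (index - 1) x spacing mm.
#'
#' @param volume a [PetVolume-class].
#' @param centerMm world coordinate of the sphere center (mm, length 3).
#' @param radiusMm sphere radius in mm.
#' @return logical 3-D array marking voxels whose centers fall inside.
#' @export
sphericalRoi <- function(volume, centerMm, radiusMm) {
  if (radiusMm <= 0) stop("radiusMm must be > 0")
  d <- dim(volume@values)
  sp <- volume@spacing
  ax <- ((seq_len(d[1L]) - 1) * sp[1L] - centerMm[1L])^2
  ay <- ((seq_len(d[2L]) - 1) * sp[2L] - centerMm[2L])^2
  az <- ((seq_len(d[3L]) - 1) * sp[3L] - centerMm[3L])^2
  dist2 <- outer(outer(ax, ay, "+"), az, "+")
  array(dist2 <= radiusMm^2, d)
}
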