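#' Output of the phantom generator
#'
#' Bundles the simulated PET volume, the organ label masks, and the
#' pre-blur ground-truth lesion supports against which segmentation
#' accuracy is judged.
#'
#' @slot volume the simulated [PetVolume-class].
#' @slot organMasks the [OrganMaskSet-class] used for physiological-uptake
#'   exclusion.
#' @slot lesionTruth list, one entry per lesion: \code{id}, \code{voxels}
#'   (integer matrix of grid indices), \code{volumeMl}, \code{peakSuv}.
#' @slot truthTable data.frame summary (id, nVoxels, volumeMl, peakSuv).
#' @export
setClass("PhantomOutput",
  representation(volume = "PetVolume", organMasks = "OrganMaskSet",
                 lesionTruth = "list", truthTable = "data.frame"))

setMethod("show", "PhantomOutput", function(object) {
  cat("PhantomOutput:", nrow(object@truthTable), "ground-truth lesions\n")
  if (nrow(object@truthTable)) print(object@truthTable)
})

#' Construct a PhantomSpec
#'
#' @param gridShape grid dimensions (length 3, each >= 8).
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @param backgroundSuv uniform background SUV.
#' @param organs data.frame with columns name (liver, spleen, kidney_left,
#'   kidney_right), cx, cy, cz, rx, ry, rz (mm), meanSuv, sdSuv. Organ
#'   uptake is drawn per voxel as Gaussian around meanSuv.
#' @param lesions data.frame with columns cx, cy, cz (mm), radius (mm),
#'   peakSuv. Lesions are uniform spheres at peakSuv before blur.
#' @param psfFwhmMm Gaussian point-spread FWHM in mm (0 disables blur).
#' @param noiseSd additive Gaussian noise SD in SUV, clipped at 0.
#' @param seed RNG seed; fixed seed gives bit-identical phantoms.
#' @return a [PhantomSpec-class].
#' @seealso [generatePhantom()], [defaultPhantomSpec()]
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 96L), spacing = c(2, 2, 2),
                        backgroundSuv = 0.8,
                        organs = emptyOrganFrame(),
                        lesions = emptyLesionFrame(),
                        psfFwhmMm = 0, noiseSd = 0, seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), backgroundSuv = backgroundSuv,
      organs = organs, lesions = lesions, psfFwhmMm = psfFwhmMm,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' @rdname phantomSpec
#' @export
emptyOrganFrame <- function() {
  data.frame(name = character(), cx = numeric(), cy = numeric(),
             cz = numeric(), rx = numeric(), ry = numeric(), rz = numeric(),
             meanSuv = numeric(), sdSuv = numeric())
}

#' @rdname phantomSpec
#' @export
emptyLesionFrame <- function() {
  data.frame(cx = numeric(), cy = numeric(), cz = numeric(),
             radius = numeric(), peakSuv = numeric())
}

#' Whole-body-like default phantom
#'
#' A 64 x 64 x 96 grid at 2 mm isotropic spacing (128 x 128 x 192 mm)
#' holding a liver (SUVmean 5), spleen, both kidneys (high physiological
#' uptake), and three spherical metastases of 7-10 mm radius with peak SUV
#' 12-20 over a 0.8 background — magnitudes chosen to straddle a typical
#' PSMA-PET scan. Default blur is a 4 mm FWHM PSF (2 voxels), default
#' noise 0.05 SUV.
#'
#' @param seed RNG seed.
#' @param psfFwhmMm,noiseSd override blur and noise.
#' @param lesions override the lesion table.
#' @return a [PhantomSpec-class].
#' @export
defaultPhantomSpec <- function(seed = 1L, psfFwhmMm = 4, noiseSd = 0.05,
                               lesions = NULL) {
  organs <- data.frame(
    name = c("liver", "spleen", "kidney_left", "kidney_right"),
    cx = c(40, 95, 90, 35), cy = c(60, 60, 70, 70),
    cz = c(130, 125, 90, 90),
    rx = c(35, 15, 10, 10), ry = c(28, 12, 8, 8), rz = c(25, 15, 14, 14),
    meanSuv = c(5, 1.8, 12, 12), sdSuv = c(0.3, 0.2, 1, 1))
  if (is.null(lesions))
    lesions <- data.frame(cx = c(30, 90, 60), cy = c(30, 30, 90),
                          cz = c(40, 60, 170), radius = c(8, 10, 7),
                          peakSuv = c(15, 20, 12))
  phantomSpec(organs = organs, lesions = lesions,
              psfFwhmMm = psfFwhmMm, noiseSd = noiseSd, seed = seed)
}

# Logical support of an ellipsoid over voxel centers.
ellipsoidMask <- function(gridShape, spacing, center, radii) {
  ax <- (((seq_len(gridShape[1L]) - 1) * spacing[1L] - center[1L]) / radii[1L])^2
  ay <- (((seq_len(gridShape[2L]) - 1) * spacing[2L] - center[2L]) / radii[2L])^2
  az <- (((seq_len(gridShape[3L]) - 1) * spacing[3L] - center[3L]) / radii[3L])^2
  array(outer(outer(ax, ay, "+"), az, "+") <= 1, gridShape)
}

# Separable Gaussian blur with replicate padding, expressed as banded
# matrix products along each axis.
gaussianBlur3d <- function(arr, fwhmMm, spacing) {
  if (fwhmMm <= 0) return(arr)
  sigmaVox <- (fwhmMm / (2 * sqrt(2 * log(2)))) / spacing
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r):r)^2 / (2 * s^2))
    w <- w / sum(w)
    n <- d[axis]
    K <- matrix(0, n, n)
    for (t in (-r):r) {
      j <- pmin(pmax(seq_len(n) + t, 1L), n)  # replicate padding
      K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w[t + r + 1L]
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    a <- array(K %*% matrix(a, n), dim(a))
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Generate a synthetic PET phantom
#'
#' Builds the volume as uniform background, per-voxel Gaussian organ
#' uptake, and uniform spherical lesions at their peak SUV; then applies
#' the Gaussian PSF blur and additive noise (clipped at 0). Ground-truth
#' lesion masks are the pre-blur lesion supports (voxel-center-in-sphere).
#' Lesions overlapping an organ are rejected as a configuration error.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomOutput-class].
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(seed = 7))
#' ph
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape
  sp <- spec@spacing
  vol <- array(spec@backgroundSuv, gs)
  labels <- array(0L, gs)
  labelMap <- integer()

  organSupport <- array(FALSE, gs)
  organMasks <- list()
  if (nrow(spec@organs)) {
    for (o in seq_len(nrow(spec@organs))) {
      row <- spec@organs[o, ]
      m <- ellipsoidMask(gs, sp, c(row$cx, row$cy, row$cz),
                         c(row$rx, row$ry, row$rz))
      if (any(m & organSupport)) stop("organ supports overlap")
      organMasks[[row$name]] <- m
      organSupport <- organSupport | m
      labels[m] <- o
      labelMap[row$name] <- o
    }
  }

  lesionTruth <- list()
  if (nrow(spec@lesions)) {
    for (l in seq_len(nrow(spec@lesions))) {
      row <- spec@lesions[l, ]
      m <- ellipsoidMask(gs, sp, c(row$cx, row$cy, row$cz),
                         rep(row$radius, 3L))
      if (!any(m)) stop("lesion ", l, " has an empty voxel support")
      if (any(m & organSupport))
        stop("lesion ", l, " overlaps an organ support")
      lesionTruth[[l]] <- list(
        id = l, voxels = which(m, arr.ind = TRUE),
        volumeMl = sum(m) * voxelVolumeMm3(sp) / 1000,
        peakSuv = row$peakSuv)
      vol[m] <- row$peakSuv
    }
  }

  vol <- withSeed(spec@seed, {
    if (length(organMasks))
      for (o in seq_len(nrow(spec@organs))) {
        m <- organMasks[[spec@organs$name[o]]]
        vol[m] <- stats::rnorm(sum(m), spec@organs$meanSuv[o],
                               spec@organs$sdSuv[o])
      }
    vol <- gaussianBlur3d(vol, spec@psfFwhmMm, sp)
    if (spec@noiseSd > 0)
      vol <- vol + stats::rnorm(length(vol), 0, spec@noiseSd)
    pmax(vol, 0)
  })

  truthTable <- data.frame(
    id = vapply(lesionTruth, `[[`, integer(1), "id"),
    nVoxels = vapply(lesionTruth, function(x) nrow(x$voxels), integer(1)),
    volumeMl = vapply(lesionTruth, `[[`, numeric(1), "volumeMl"),
    peakSuv = vapply(lesionTruth, `[[`, numeric(1), "peakSuv"))

  new("PhantomOutput",
      volume = petVolume(vol, sp, scanId = paste0("phantom", spec@seed)),
      organMasks = organMaskSet(labels, labelMap),
      lesionTruth = lesionTruth, truthTable = truthTable)
}
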