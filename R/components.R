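# 3-D connected-component labeling under 26-connectivity.
#
# PET hot-spot labeling conventionally uses the full 26-neighbourhood so
# that diagonally touching voxels belong to one focus; the same
# connectivity is used at detection and at isocontour refinement so the
# two stages agree.

# The 26 neighbour offsets (all sign combinations except the origin).
neighborOffsets26 <- local({
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
})

#' Label 26-connected components of a 3-D mask
#'
#' Breadth-first labeling of the \code{TRUE} voxels of a logical 3-D
#' array. Components are numbered 1, 2, ... in order of their smallest
#' linear (column-major) voxel index, so the labeling is deterministic.
#'
#' @param mask logical 3-D array.
#' @return integer array of the same shape; 0 outside the mask.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1, 1, 1] <- TRUE; m[4, 4, 4] <- TRUE
#' table(labelComponents(m))
#' @export
labelComponents <- function(mask) {
  dims <- dim(mask)
  if (length(dims) != 3L) stop("mask must be a 3-D array")
  labels <- integer(length(mask))
  active <- which(mask)
  if (!length(active)) return(array(labels, dims))
  inMask <- as.logical(mask)
  lab <- 0L
  for (seed in active) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier)) {
      nb <- neighborLinear(frontier, dims)
      nb <- nb[inMask[nb] & labels[nb] == 0L]
      if (!length(nb)) break
      nb <- unique(nb)
      labels[nb] <- lab
      frontier <- nb
    }
  }
  array(labels, dims)
}

# All in-bounds 26-neighbours (linear indices, possibly duplicated) of a
# set of voxels given by linear indices.
neighborLinear <- function(idx, dims) {
  co <- linearToCoords(idx, dims)
  n <- nrow(co)
  off <- neighborOffsets26
  nb <- co[rep(seq_len(n), times = nrow(off)), , drop = FALSE] +
    off[rep(seq_len(nrow(off)), each = n), , drop = FALSE]
  ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
  coordsToLinear(nb[ok, , drop = FALSE], dims)
}

# Voxels of the component of `mask` containing `seedIdx` (linear index).
# Returns sorted linear indices; errors if the seed is outside the mask.
componentContaining <- function(mask, seedIdx) {
  dims <- dim(mask)
  if (!mask[seedIdx]) stop("seed voxel is not inside the mask")
  inComp <- logical(length(mask))
  inComp[seedIdx] <- TRUE
  frontier <- seedIdx
  while (length(frontier)) {
    nb <- neighborLinear(frontier, dims)
    nb <- nb[mask[nb] & !inComp[nb]]
    if (!length(nb)) break
    nb <- unique(nb)
    inComp[nb] <- TRUE
    frontier <- nb
  }
  which(inComp)
}
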