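# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Population (divide-by-n) standard deviation.
popSd <- function(x) sqrt(mean((x - mean(x))^2))

# Voxel volume in mm^3 for a spacing triple.
voxelVolumeMm3 <- function(spacing) prod(spacing)

stopIfNot3dCongruent <- function(volume, masks) {
  if (!identical(dim(volume@values), dim(masks@labels)))
    stop("organ mask grid is not congruent with the PET volume grid")
  invisible(TRUE)
}

# Linear index <-> (i,j,k) coordinate helpers for a 3-D grid.
coordsToLinear <- function(coords, dims) {
  (coords[, 3L] - 1L) * (dims[1L] * dims[2L]) +
    (coords[, 2L] - 1L) * dims[1L] + coords[, 1L]
}

linearToCoords <- function(idx, dims) {
  idx0 <- idx - 1L
  k <- idx0 %/% (dims[1L] * dims[2L])
  r <- idx0 %% (dims[1L] * dims[2L])
  j <- r %/% dims[1L]
  i <- r %% dims[1L]
  cbind(i + 1L, j + 1L, k + 1L)
}
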