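# Independent brute-force oracles. These deliberately use scalar loops
# and direct definitions so they share no code path with the package.

# 26-neighbour offsets as a plain list of triples.
oracleOffsets <- local({
  out <- list()
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
    if (di != 0 || dj != 0 || dk != 0)
      out[[length(out) + 1L]] <- c(di, dj, dk)
  out
})

# Stack-based scalar flood fill labeling of a logical 3-D array.
oracleLabelComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextLab <- 0L
  for (idx in which(mask)) {
    if (lab[idx] != 0L) next
    nextLab <- nextLab + 1L
    stack <- list(arrayInd(idx, d)[1, ])
    lab[idx] <- nextLab
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (off in oracleOffsets) {
        w <- v + off
        if (any(w < 1L) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nextLab
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# Canonical representation of a labeling: list of sorted linear-index
# sets, ordered by their smallest member.
componentSets <- function(lab) {
  sets <- lapply(split(which(lab > 0L), lab[lab > 0L]), sort)
  sets[order(vapply(sets, min, numeric(1)))]
}

# Brute-force 50 percent-of-local-SUVmax refinement: threshold scan plus
# scalar flood fill from the focus' hottest voxel.
oracleRefine <- function(values, focusLin) {
  d <- dim(values)
  localMax <- max(values[focusLin])
  mask <- values >= 0.5 * localMax
  seed <- focusLin[which.max(values[focusLin])]
  lab <- oracleLabelComponents(mask)
  sort(which(lab == lab[seed]))
}

# Direct per-cutoff maximally selected rank statistic: log-rank scores
# from a hand-rolled Nelson-Aalen, conditional standardization, scan over
# admissible midpoints.
oracleMaxstat <- function(time, event, x, minProp = 0.1) {
  n <- length(time)
  H <- numeric(n)
  for (i in seq_len(n)) {
    h <- 0
    for (t in sort(unique(time[event == 1]))) {
      if (t > time[i]) break
      h <- h + sum(event == 1 & time == t) / sum(time >= t)
    }
    H[i] <- h
  }
  a <- event - H
  xs <- sort(unique(x))
  best <- NULL
  for (i in seq_len(length(xs) - 1L)) {
    cut <- (xs[i] + xs[i + 1L]) / 2
    m <- sum(x <= cut)
    if (m < ceiling(minProp * n) || (n - m) < ceiling(minProp * n)) next
    Tm <- sum(a[x <= cut])
    E <- m * mean(a)
    V <- m * (n - m) / (n - 1) * mean((a - mean(a))^2)
    z <- abs(Tm - E) / sqrt(V)
    if (is.null(best) || z > best$z + 1e-12)  # strict: first max wins ties
      best <- list(cutoff = cut, z = z)
  }
  best
}

# Smooth deterministic 3-D test field with several bumps.
smoothField <- function(d, scale = 6, phase = 0) {
  i <- seq_len(d[1]); j <- seq_len(d[2]); k <- seq_len(d[3])
  f <- outer(outer(sin(i / 3 + phase), cos(j / 4 + phase), "+"),
             sin(k / 5 + 2 * phase), "+")
  scale * (f - min(f)) / (max(f) - min(f))
}

# Hand-worked Kaplan-Meier fixture: group A events at 2 and 4, censored
# at 6 (median 4); group B events at 10, 12, 14 (median 12).
kmFixture <- function() {
  data.frame(os_months = c(2, 4, 6, 10, 12, 14),
             event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
             group = rep(c("A", "B"), each = 3))
}

# Random small survival fixture for oracle comparisons.
randomSurvivalFixture <- function(n, seed) {
  set.seed(seed)
  data.frame(os_months = round(rexp(n, 1 / 12), 1) + 0.1,
             event = runif(n) < 0.7,
             x = round(rlnorm(n, 3, 1), 2))
}

# Coordinate matrix (i, j, k rows) -> column-major linear indices.
coordsFromMatrix <- function(m, dims = c(64L, 64L, 96L)) {
  as.integer((m[, 3] - 1) * dims[1] * dims[2] + (m[, 2] - 1) * dims[1] +
               m[, 1])
}

# Synthetic LesionSegment built directly from slots (volumes in ml).
makeLesion <- function(id, nVox, suvVals, voxelVolMm3 = 8) {
  vox <- cbind(seq_len(nVox), 1L, 1L)
  vml <- nVox * voxelVolMm3 / 1000
  new("LesionSegment", lesionId = as.integer(id), voxels = vox,
      suvMax = max(suvVals), suvMean = mean(suvVals), volumeMl = vml,
      tlqLesion = vml / mean(suvVals))
}
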