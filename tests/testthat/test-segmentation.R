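test_that("liver threshold formula matches its printed form", {
  expect_identical(computeThreshold(4.3, 0), 4.3)
  expect_equal(computeThreshold(5, 1), 5.16, tolerance = 1e-12)
  expect_equal(computeThreshold(2, 0.5), 5.375, tolerance = 1e-12)
  # collapses to the constant for any noise-free liver
  for (m in c(0.3, 1, 5.7, 42))
    expect_equal(computeThreshold(m, 0), 4.3, tolerance = 1e-12)
  # strictly increasing in the liver sd
  expect_true(all(diff(sapply(c(0, 0.5, 1, 2),
                              function(s) computeThreshold(5, s))) > 0))
  expect_error(computeThreshold(0, 1), "liverSuvMean")
  expect_error(computeThreshold(5, -1), "liverSuvSd")
})

test_that("liver reference statistics use the declared sd convention", {
  vals <- array(1, c(8, 8, 8))
  vals[1:2, 1, 1] <- c(4, 6)
  labs <- array(0L, c(8, 8, 8))
  labs[1:2, 1, 1] <- 1L
  vol <- petVolume(vals, spacing = 2)
  masks <- organMaskSet(labs, c(liver = 1L))
  rs <- liverReferenceStats(vol, masks)
  expect_equal(rs@liverSuvMean, 5)
  expect_equal(rs@liverSuvSd, 1)          # population convention on {4, 6}
  expect_equal(rs@threshold, 5.16, tolerance = 1e-12)
  rsS <- liverReferenceStats(vol, masks, sdConvention = "sample")
  expect_equal(rsS@liverSuvSd, sqrt(2))
  # uniform liver: sd 0, threshold 4.3
  vals[1:2, 1, 1] <- 5
  rs0 <- liverReferenceStats(petVolume(vals, 2), masks)
  expect_equal(rs0@threshold, 4.3)
  # no liver label is an error
  expect_error(liverReferenceStats(vol, organMaskSet(labs, c(spleen = 1L))),
               "liver")
})

test_that("focus detection finds the 26-connected supra-threshold sets", {
  vals <- array(1, c(10, 10, 10))
  vol <- petVolume(vals, 2)
  expect_length(detectFoci(vol, 4.3), 0)
  # two disjoint blobs, one diagonal-touching pair (26-connected: one focus)
  vals[2:3, 2:3, 2:3] <- 10
  vals[8, 8, 8] <- 6
  vals[9, 9, 9] <- 7
  vol <- petVolume(vals, 2)
  foci <- detectFoci(vol, 4.3)
  expect_length(foci, 2)
  expect_equal(sort(sapply(foci, `[[`, "suvMax")), c(7, 10))
  # minimum size filter drops the 2-voxel focus
  expect_length(detectFoci(vol, 4.3, minVoxels = 3L), 1)
})

test_that("physiological foci are excluded by organ overlap", {
  vals <- array(1, c(12, 12, 12))
  vals[2:4, 2:4, 2:4] <- 10        # inside kidney mask
  vals[9:10, 9:10, 9:10] <- 10     # free metastasis
  labs <- array(0L, c(12, 12, 12))
  labs[1:5, 1:5, 1:5] <- 1L
  vol <- petVolume(vals, 2)
  masks <- organMaskSet(labs, c(kidney_left = 1L))
  foci <- detectFoci(vol, 4.3)
  kept <- excludePhysiological(foci, masks)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$voxels[1, ], c(9L, 9L, 9L),
               ignore_attr = TRUE)
  # explicit exclusion removes the remaining focus too
  expect_length(excludePhysiological(foci, masks,
                                     reviewAdjustments(excludeFoci = 1:2)),
                0)
  # include-region seed re-inserts a focus inside the organ
  adj <- reviewAdjustments(includeRegions = matrix(c(3L, 3L, 3L), 1))
  back <- excludePhysiological(list(), masks, adj, volume = vol)
  expect_length(back, 1)
  expect_equal(back[[1]]$suvMax, 10)
  expect_error(excludePhysiological(list(), masks,
    reviewAdjustments(includeRegions = matrix(c(99L, 1L, 1L), 1)),
    volume = vol), "outside the grid")
})

test_that("a metastasis abutting an organ survives the overlap rule", {
  vals <- array(1, c(12, 12, 12))
  vals[4:9, 5, 5] <- 10            # 6 voxels, 2 inside the organ
  labs <- array(0L, c(12, 12, 12))
  labs[1:5, 1:12, 1:12] <- 1L
  foci <- detectFoci(petVolume(vals, 2), 4.3)
  expect_length(excludePhysiological(foci, organMaskSet(labs,
                                                        c(liver = 1L))), 1)
  # with 4 of 6 voxels inside, the focus is removed
  vals2 <- array(1, c(12, 12, 12))
  vals2[2:7, 5, 5] <- 10
  foci2 <- detectFoci(petVolume(vals2, 2), 4.3)
  expect_length(excludePhysiological(foci2, organMaskSet(labs,
                                                         c(liver = 1L))), 0)
})

test_that("50 percent refinement matches brute force on worked shapes", {
  # uniform cube in zero-ish background refines to exactly the cube
  vals <- array(0.1, c(12, 12, 12))
  vals[4:7, 4:7, 4:7] <- 10
  vol <- petVolume(vals, 2)
  foci <- detectFoci(vol, 4.3)
  les <- refineLesion(vol, foci[[1]])
  expect_equal(nrow(lesionVoxels(les)), 64)
  expect_equal(suvMean(les), 10)
  expect_equal(volumeMl(les), 64 * 8 / 1000)
  expect_equal(tlqLesion(les), volumeMl(les) / suvMean(les))

  # linear radial falloff, peak 20: refined set = voxels with SUV >= 10
  d <- c(17, 17, 17)
  vals <- array(0, d)
  for (i in 1:17) for (j in 1:17) for (k in 1:17) {
    r <- sqrt(sum((c(i, j, k) - 9)^2)) * 2
    vals[i, j, k] <- max(0, 20 * (1 - r / 14))
  }
  vol <- petVolume(vals, 2)
  foci <- detectFoci(vol, 4.3)
  les <- refineLesion(vol, foci[[1]])
  lin <- sort(which(array(vals >= 10, d)))
  got <- sort(as.integer((lesionVoxels(les)[, 3] - 1L) * 17L * 17L +
                (lesionVoxels(les)[, 2] - 1L) * 17L +
                lesionVoxels(les)[, 1]))
  expect_identical(got, lin)
  expect_identical(sort(oracleRefine(vals,
    which(vals > 4.3))), lin)
})

test_that("merged 50 percent isocontours deduplicate to one lesion", {
  vals <- array(0.1, c(20, 8, 8))
  vals[4:6, 4, 4] <- 10
  vals[7:11, 4, 4] <- 6     # bridge below detection, above half-max
  vals[12:14, 4, 4] <- 10.5
  labs <- array(0L, c(20, 8, 8))
  vol <- petVolume(vals, 2)
  masks <- organMaskSet(labs, c(liver = 1L))
  foci <- detectFoci(vol, 8)
  expect_length(foci, 2)
  seg <- segmentScan(vol, masks, threshold = 8)
  expect_length(seg$lesions, 1)
  expect_equal(nrow(lesionVoxels(seg$lesions[[1]])), 11)
})

test_that("whole-scan segmentation recovers clean phantom lesions exactly", {
  ph <- generatePhantom(defaultPhantomSpec(seed = 3, psfFwhmMm = 0,
                                           noiseSd = 0))
  seg <- segmentScan(ph@volume, ph@organMasks)
  expect_length(seg$lesions, nrow(ph@truthTable))
  got <- sort(sapply(seg$lesions, volumeMl))
  expect_equal(got, sort(ph@truthTable$volumeMl))
  # sorted by descending volume, every lesion above the scan threshold
  vols <- sapply(seg$lesions, volumeMl)
  expect_identical(vols, sort(vols, decreasing = TRUE))
  expect_true(all(sapply(seg$lesions, suvMax) > seg$threshold))
  # deterministic and idempotent
  seg2 <- segmentScan(ph@volume, ph@organMasks)
  expect_identical(lesionTable(seg$lesions), lesionTable(seg2$lesions))
})

test_that("a lesion placed inside an organ mask needs an include seed", {
  spec <- phantomSpec(gridShape = c(24, 24, 24), spacing = 2,
                      backgroundSuv = 0.5,
                      organs = data.frame(name = "spleen", cx = 22, cy = 22,
                                          cz = 22, rx = 14, ry = 14, rz = 14,
                                          meanSuv = 2, sdSuv = 0.1),
                      lesions = emptyLesionFrame(),
                      psfFwhmMm = 0, noiseSd = 0, seed = 4)
  ph <- generatePhantom(spec)
  vals <- suvValues(ph@volume)
  vals[10:12, 10:12, 10:12] <- 18   # hot focus inside the spleen
  vol <- petVolume(vals, 2)
  seg <- segmentScan(vol, ph@organMasks, threshold = 4.3)
  expect_length(seg$lesions, 0)
  adj <- reviewAdjustments(includeRegions = matrix(c(11L, 11L, 11L), 1))
  seg2 <- segmentScan(vol, ph@organMasks, adjustments = adj,
                      threshold = 4.3)
  expect_length(seg2$lesions, 1)
  expect_equal(suvMax(seg2$lesions[[1]]), 18)
})

test_that("component labeling agrees with the flood-fill oracle", {
  for (s in 1:6) {
    set.seed(100 + s)
    d <- sample(8:16, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.25, d)
    expect_identical(componentSets(labelComponents(mask)),
                     componentSets(oracleLabelComponents(mask)))
  }
})

test_that("NIfTI round trip preserves the volume and spacing", {
  ph <- generatePhantom(defaultPhantomSpec(seed = 6))
  f <- tempfile(fileext = ".nii.gz")
  writePetVolume(ph@volume, f)
  back <- readPetVolume(f, timepoint = "baseline")
  expect_equal(suvValues(back), suvValues(ph@volume), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(voxelSpacing(back), voxelSpacing(ph@volume))
  unlink(f)
})
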