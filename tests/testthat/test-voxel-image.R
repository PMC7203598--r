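test_that("image round trips preserve values and spacing across formats", {
  img <- VoxelImage(array(sample(0:4095, 5 * 5 * 5, replace = TRUE),
                          c(5, 5, 5)), spacing = 10.4)
  tmp <- withr::local_tempdir()
  pMhd <- file.path(tmp, "a.mhd")
  pNii <- file.path(tmp, "a.nii")
  pTif <- file.path(tmp, "a.tif")
  writeVoxelImage(img, pMhd)
  writeVoxelImage(img, pNii)
  writeVoxelImage(img, pTif)
  rMhd <- readVoxelImage(pMhd)
  expect_identical(imgData(rMhd), imgData(img))
  expect_equal(spacing(rMhd), 10.4)
  rNii <- readVoxelImage(pNii)
  expect_equal(imgData(rNii), imgData(img))
  expect_equal(spacing(rNii), 10.4, tolerance = 1e-6)
  rTif <- readVoxelImage(pTif, spacing = 10.4)
  expect_equal(imgData(rTif), imgData(img))
  # cross-format: all readers yield voxelwise-equal volumes
  expect_equal(imgData(rMhd), imgData(rTif))
  # TIFF with no spacing metadata and no override
  expect_error(readVoxelImage(pTif), "spacing")
})

test_that("constant volume survives a write/read cycle unchanged", {
  img <- VoxelImage(array(7, c(5, 5, 5)), spacing = 12)
  tmp <- withr::local_tempdir()
  writeVoxelImage(img, file.path(tmp, "c.mhd"))
  back <- readVoxelImage(file.path(tmp, "c.mhd"))
  expect_identical(imgData(back), imgData(img))
  expect_equal(spacing(back), 12)
})

test_that("densitometric calibration is an exact affine map with inverse", {
  img <- VoxelImage(array(c(0, 1, 250, 4095), c(4, 1, 1)))
  # identity calibration leaves the image unchanged
  expect_identical(imgData(greyToTmd(img, densitometricCalibration(1, 0))),
                   imgData(img))
  cal <- densitometricCalibration(slope = 0.72, intercept = -195.4)
  tmd <- greyToTmd(img, cal)
  expect_equal(imgUnit(tmd), "mg/cc")
  # grey 0 maps to the intercept
  expect_equal(imgData(tmd)[1], -195.4)
  # round trip within 1e-9 of the grey range
  set.seed(11)
  r <- VoxelImage(array(runif(1000, 0, 4095), c(10, 10, 10)))
  back <- tmdToGrey(greyToTmd(r, cal), cal)
  expect_lt(max(abs(imgData(back) - imgData(r))), 1e-9 * 4095)
  expect_error(densitometricCalibration(slope = -1), "slope")
})

test_that("threshold sits midway between two spike modes", {
  v <- c(rep(100, 500), rep(300, 400))
  img <- VoxelImage(array(v, c(30, 30, 1)))
  h <- greyHistogram(img)
  expect_equal(sum(h@counts), 900)
  expect_equal(computeThreshold(h), 200)
})

test_that("threshold of a two-Gaussian mixture lands at the component-mean midpoint", {
  set.seed(99)
  n <- 1e6
  v <- c(rnorm(n / 2, 150, 30), rnorm(n / 2, 850, 60))
  img <- VoxelImage(array(round(v), c(100, 100, 100)))
  h <- greyHistogram(img, binWidth = 4)
  thr <- computeThreshold(h)
  # exhaustive scan of the histogram for its two modes
  pk <- order(h@counts, decreasing = TRUE)
  lowPeak <- h@mids[pk[which(h@mids[pk] < 500)[1]]]
  highPeak <- h@mids[pk[which(h@mids[pk] > 500)[1]]]
  expect_lt(abs(thr - (lowPeak + highPeak) / 2), 2 * h@binWidth)
  expect_lt(abs(thr - (150 + 850) / 2), 3 * h@binWidth)
})

test_that("threshold detection rejects non-bimodal histograms", {
  flat <- VoxelImage(array(rep(1:100, each = 10), c(10, 10, 10)))
  expect_error(computeThreshold(greyHistogram(flat)), "bimodal|valley")
})

test_that("threshold is invariant under rescaling of the counts", {
  set.seed(4)
  v <- round(c(rnorm(5e4, 120, 25), rnorm(5e4, 880, 50)))
  h <- greyHistogram(VoxelImage(array(v, c(100, 100, 10))), binWidth = 5)
  h2 <- new("GreyHistogram", mids = h@mids, counts = h@counts * 17.3,
            binWidth = h@binWidth)
  expect_equal(computeThreshold(h), computeThreshold(h2))
})

test_that("transition zone matches a brute-force outward scan", {
  mids <- 1:9
  counts <- c(80, 60, 40, 20, 10, 15, 25, 50, 90)
  h <- new("GreyHistogram", mids = mids, counts = counts, binWidth = 1)
  tz <- computeTransitionZone(h, threshold = 5)
  ref <- refTransitionZone(mids, counts, 5)
  expect_equal(unname(tz), unname(ref))
  # counts at least twice the threshold-bin count: the 20-count bin (20 >=
  # 2 x 10) below and the 25-count bin above
  expect_equal(unname(tz), c(4, 7))
})

test_that("transition zone handles degenerate and monotone histograms", {
  # zero count at the threshold bin: immediate neighbours qualify
  h0 <- new("GreyHistogram", mids = 1:5, counts = c(9, 3, 0, 4, 8),
            binWidth = 1)
  expect_equal(unname(computeTransitionZone(h0, 3)), c(2, 4))
  # monotone counts on both sides: first bins satisfying the 2x rule
  hm <- new("GreyHistogram", mids = 1:11,
            counts = c(64, 32, 16, 8, 4, 2, 5, 9, 17, 33, 65), binWidth = 1)
  tz <- computeTransitionZone(hm, 6)
  expect_equal(unname(tz), unname(refTransitionZone(1:11, hm@counts, 6)))
  # no qualifying bin on one side: histogram extreme with a warning
  hedge <- new("GreyHistogram", mids = 1:5, counts = c(50, 25, 10, 11, 12),
               binWidth = 1)
  expect_warning(tzE <- computeTransitionZone(hedge, 3), "maximum")
  expect_equal(unname(tzE), c(2, 5))
})

test_that("binarisation uses a strict inequality and matches tube geometry", {
  img <- VoxelImage(array(c(1, 2, 3, 3, 4, 5), c(6, 1, 1)))
  m <- binarise(img, 3)
  expect_equal(sum(imgData(m)), 2) # voxels exactly at the threshold -> background
  expect_false(any(imgData(binarise(img, 10))))
  # phantom with known tube geometry, no blur/noise: mask count equals the
  # analytic voxelisation count
  seg <- segmentImage(cleanPhantom)
  mC <- binarise(cleanPhantom, seg@threshold)
  expect_equal(sum(imgData(mC)), sum(imgData(phantomMask(cleanSpec))))
})

test_that("affine recalibration commutes with binarisation", {
  cal <- densitometricCalibration(0.7, 100)
  thr <- tinySeg@threshold
  m1 <- binarise(tinyPhantom, thr)
  m2 <- binarise(greyToTmd(tinyPhantom, cal), cal@slope * thr + cal@intercept)
  expect_identical(imgData(m1), imgData(m2))
})

test_that("longitudinal cropping keeps floor(fraction x occupied slices)", {
  d <- c(4, 4, 120)
  a <- array(0, d)
  a[2, 2, 11:110] <- 10 # 100 occupied slices
  img <- VoxelImage(a)
  full <- cropLongitudinalFraction(img, 1, "proximal", threshold = 5)
  expect_equal(dim(full)[3], 100)
  crop <- cropLongitudinalFraction(img, 0.8, "proximal", threshold = 5)
  expect_equal(dim(crop)[3], 80)
  # proximal = high z: retained slices are the top of the extent
  expect_true(all(imgData(crop)[2, 2, ] == 10))
  cropD <- cropLongitudinalFraction(img, 0.33, "distal", threshold = 5)
  expect_equal(dim(cropD)[3], floor(0.33 * 100))
  expect_error(cropLongitudinalFraction(img, 0, "proximal", 5), "fraction")
  expect_error(cropLongitudinalFraction(img, 1.2, "proximal", 5), "fraction")
})

test_that("alignment recovers an integer shift and is idempotent", {
  # an off-centre blob with margins so the shifted copy stays inside
  base <- array(0, c(24, 24, 24))
  base[6:12, 8:15, 7:14] <- 900
  ref <- VoxelImage(base, 40)
  shifted <- BoneAdapt:::.shiftArray(base, c(3L, -2L, 5L), 0)
  mov <- VoxelImage(shifted, 40)
  thr <- 500
  al <- alignForComparison(ref, mov, thr)
  expect_equal(al$shift, c(-3L, 2L, -5L))
  expect_identical(dim(al$reference), dim(al$moving))
  expect_equal(overlapRatio(binarise(al$reference, thr),
                            binarise(al$moving, thr)), 1)
  # aligning the aligned pair again yields zero shift
  al2 <- alignForComparison(al$reference, al$moving, thr)
  expect_equal(al2$shift, c(0L, 0L, 0L))
  expect_error(alignForComparison(ref, VoxelImage(array(0, dim(base))), thr),
               "empty")
})

test_that("aligned outputs share the union bounding box dimensions", {
  a <- array(0, c(12, 12, 12)); a[2:4, 2:4, 2:4] <- 10
  b <- array(0, c(12, 12, 12)); b[8:11, 8:11, 8:11] <- 10
  al <- alignForComparison(VoxelImage(a), VoxelImage(b), 5)
  expect_identical(dim(al$reference), dim(al$moving))
})

test_that("largest component selection agrees with reference labelling", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:5, 2:5, 2:5] <- TRUE  # 64 voxels
  m[8:9, 8:9, 8] <- TRUE    # 4 voxels
  bm <- BoneMask(m, 10)
  keep <- largestComponent(bm)
  expect_equal(sum(imgData(keep)), 64)
  # single component unchanged
  one <- BoneMask(array(TRUE, c(3, 3, 3)), 10)
  expect_identical(imgData(largestComponent(one)), imgData(one))
  expect_error(largestComponent(BoneMask(array(FALSE, c(2, 2, 2)), 10)),
               "empty")
  # speckle + tube: result equals the tube, cross-checked against the
  # reference component labelling
  tube <- imgData(phantomMask(cleanSpec))
  speckled <- tube
  set.seed(3)
  bg <- which(!BoneAdapt:::.faceDilate(tube)) # background clear of the tube
  speckled[sample(bg, 25)] <- TRUE
  lab <- refLabelComponents(speckled)
  big <- which.max(tabulate(lab[lab > 0]))
  got <- largestComponent(BoneMask(speckled, 40))
  expect_identical(imgData(got), array(lab == big, dim(tube)))
  expect_identical(imgData(got), tube)
})

test_that("segmentation model serialises to plain text and back", {
  seg <- segmentationModel(556.7, 540.2, 580.9)
  tmp <- withr::local_tempfile()
  writeSegmentationModel(seg, tmp)
  back <- readSegmentationModel(tmp)
  expect_equal(back@threshold, 556.7)
  expect_equal(back@tzLow, 540.2)
  expect_equal(back@tzHigh, 580.9)
  expect_error(segmentationModel(10, 20, 30), "tzLow")
})
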