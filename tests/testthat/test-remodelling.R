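test_that("mechanoregulation response is linear with an inclusive lazy band", {
  p <- remodellingParams(B = 0.19, k = 11.7)
  expect_equal(deltaTmd(11.7, p), 0)
  # calibrated rate and apposition limit, stimulus 10 Pa above the limit
  expect_equal(deltaTmd(21.7, p), 0.19 * 10)
  expect_equal(deltaTmd(1.7, p), -0.19 * 10)
  plz <- remodellingParams(B = 0.19, k = 11.7, w = 5)
  expect_equal(deltaTmd(11.7 + 4, plz), 0)
  expect_equal(deltaTmd(11.7 + 5, plz), 0)       # band edge inclusive
  expect_equal(deltaTmd(11.7 + 6, plz), 0.19 * 6)
  expect_equal(deltaTmd(11.7 - 6, plz), -0.19 * 6)
  # w = 0 reproduces the base model over a stimulus sweep
  theta <- seq(0, 40, by = 0.5)
  expect_equal(deltaTmd(theta, remodellingParams(B = 0.19, k = 11.7, w = 0)),
               deltaTmd(theta, p))
})

test_that("SED apposition limits convert to the expected microstrain", {
  expect_equal(signif(sedToMicrostrain(4.86, 14.8e9), 3), 25.6)
  expect_equal(signif(sedToMicrostrain(11.7, 14.8e9), 3), 39.8)
  expect_equal(sedToMicrostrain(0), 0)
  expect_error(sedToMicrostrain(-1), "non-negative")
})

test_that("TMD clamp limits values to the physical range", {
  p <- remodellingParams(B = 1, k = 1)
  img <- VoxelImage(array(c(-20, 0, 700, 1400, 1500, 2e4), c(6, 1, 1)),
                    unit = "mg/cc")
  out <- applyClamp(img, p)
  expect_equal(as.vector(imgData(out)), c(0, 0, 700, 1400, 1400, 1400))
})

test_that("a single BRU drives its 8-voxel mean exactly to the target", {
  # 2x2x2 block of voxels: 4 bone at 800, 4 background slightly above zero;
  # the central lattice node is the only full-coverage BRU
  a <- array(0, c(2, 2, 2))
  a[, , 1] <- 800
  a[, , 2] <- 1e-3
  img <- VoxelImage(a, spacing = 40, unit = "mg/cc")
  seg <- segmentationModel(400, 300, 500)
  mask <- binarise(img, seg@threshold)
  delta <- 8
  p <- remodellingParams(B = 1, k = 0) # theta = delta gives dTMD = delta
  st <- surfaceStimulusField(mask, delta, "sed")
  central <- st@nodeIJK[, 1] == 1 & st@nodeIJK[, 2] == 1 & st@nodeIJK[, 3] == 1
  expect_equal(sum(central), 1)
  # restrict the field to the single central node (a subset of the surface)
  st@values <- st@values[central]
  st@nodeIJK <- st@nodeIJK[central, , drop = FALSE]
  out <- bruUpdate(img, seg, st, p)
  # hand arithmetic: target mean = mean + 8; only background scaled (after
  # flooring at 1 mg/cc): c = (8*(mean + 8) - 3200) / 4, one proposal per
  # voxel, so each background voxel becomes c * 1
  cFac <- (8 * (mean(a) + delta) - 3200) / 4
  expect_equal(imgData(out)[, , 1], a[, , 1], tolerance = 1e-12)
  expect_equal(unname(imgData(out)[1, 1, 2]), cFac, tolerance = 1e-9)
  # commanded 8-voxel mean hit exactly
  expect_equal(mean(imgData(out)), mean(a) + delta, tolerance = 1e-9)
})

test_that("clamp bounds and BRU monotonicity hold under random stimuli", {
  img <- VoxelImage(imgData(greyToTmd(cleanPhantom, idCal)),
                    spacing = 40, unit = "mg/cc")
  seg <- segmentImage(cleanPhantom)
  mask <- binarise(img, seg@threshold)
  set.seed(5)
  st <- surfaceStimulusField(mask, runif(1, 0, 50), "sed")
  st@values <- runif(length(st@values), 0, 60)
  p <- remodellingParams(B = 0.3, k = 30)
  out <- bruUpdate(img, seg, st, p)
  expect_true(all(imgData(out) >= 0 & imgData(out) <= 1400))
  # monotonicity: raising theta at one node never lowers that BRU's mean
  d <- dim(imgData(img))
  i0 <- 10L
  st2 <- st
  st2@values[i0] <- st@values[i0] + 20
  out2 <- bruUpdate(img, seg, st2, p)
  n <- st@nodeIJK[i0, ]
  vox <- expand.grid(i = n[1] + (-1:0), j = n[2] + (-1:0), k = n[3] + (-1:0))
  keep <- vox$i >= 0 & vox$j >= 0 & vox$k >= 0 &
    vox$i < d[1] & vox$j < d[2] & vox$k < d[3]
  sel <- as.matrix(vox[keep, ]) + 1L
  expect_gte(mean(imgData(out2)[sel]), mean(imgData(out)[sel]) - 1e-12)
})

test_that("a BRU with exact arithmetic: mean hits the target pre-clamp", {
  # isolated 8-voxel block, one interior node, moderate resorption
  a <- array(c(rep(900, 6), 450, 120), c(2, 2, 2))
  img <- VoxelImage(a, spacing = 40, unit = "mg/cc")
  seg <- segmentationModel(500, 400, 600)
  mask <- binarise(img, seg@threshold)
  st <- surfaceStimulusField(mask, 0, "sed")
  central <- st@nodeIJK[, 1] == 1 & st@nodeIJK[, 2] == 1 & st@nodeIJK[, 3] == 1
  st@values <- st@values[central]
  st@nodeIJK <- st@nodeIJK[central, , drop = FALSE]
  p <- remodellingParams(B = 1, k = 12) # theta 0 -> dTMD = -12
  out <- bruUpdate(img, seg, st, p)
  # resorption scales bone + TZ voxels (everything but the 120 background)
  newMean <- mean(a) - 12
  cFac <- (8 * newMean - 120) / sum(c(rep(900, 6), 450))
  expect_equal(mean(imgData(out)), newMean, tolerance = 1e-9)
  expect_equal(unname(imgData(out)[2, 2, 2]), 120, tolerance = 1e-12)
  expect_equal(unname(imgData(out)[1, 1, 1]), 900 * cFac, tolerance = 1e-9)
})

test_that("interior voxels are never modified by the update", {
  img <- greyToTmd(cleanPhantom, idCal)
  seg <- segmentImage(cleanPhantom)
  mask <- binarise(img, seg@threshold)
  st <- surfaceStimulusField(mask, 45, "sed")
  p <- remodellingParams(B = 0.5, k = 30)
  out <- bruUpdate(img, seg, st, p)
  # voxels with no incident surface node: interior of the wall and far
  # background; compute the contributing-voxel set from the node list
  d <- dim(imgData(img))
  touched <- array(FALSE, d)
  for (r in seq_len(nrow(st@nodeIJK))) {
    n <- st@nodeIJK[r, ]
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      i <- n[1] + di; j <- n[2] + dj; k <- n[3] + dk
      if (i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3])
        touched[i, j, k] <- TRUE
    }
  }
  untouched <- !touched
  expect_gt(sum(untouched), 0)
  expect_identical(imgData(out)[untouched], imgData(img)[untouched])
})

test_that("zero rate and on-limit stimulus leave the image voxel-identical", {
  seg <- tinySeg
  # B = 0 through the full simulation step
  out0 <- simulateStep(tinyPhantom, seg, idCal, 20,
                       remodellingParams(B = 0, k = 30), "sed",
                       stimulus = tinyStimulus)
  expect_identical(imgData(out0), imgData(tinyPhantom))
  # theta == k everywhere, w = 0
  mask <- binarise(tinyPhantom, seg@threshold)
  img <- greyToTmd(tinyPhantom, idCal)
  st <- surfaceStimulusField(largestComponent(mask), 17.3, "sed")
  outK <- bruUpdate(img, seg, st, remodellingParams(B = 0.4, k = 17.3))
  expect_identical(imgData(outK), imgData(img))
})

test_that("all-zero stimulus resorbs: bone volume never increases", {
  seg <- tinySeg
  mask <- largestComponent(binarise(tinyPhantom, seg@threshold))
  st <- surfaceStimulusField(mask, 0, "sed")
  p <- remodellingParams(B = 0.4, k = 30)
  out <- simulateStep(tinyPhantom, seg, idCal, 20, p, "sed", stimulus = st)
  bv0 <- sum(imgData(binarise(tinyPhantom, seg@threshold)))
  bv1 <- sum(imgData(binarise(out, seg@threshold)))
  expect_lte(bv1, bv0)
})

test_that("the lazy-zone model with w = 0 equals the base model", {
  p0 <- remodellingParams(B = 0.25, k = 30, w = 0)
  img <- greyToTmd(tinyPhantom, idCal)
  out0 <- bruUpdate(img, tinySeg, tinyStimulus, p0)
  outBase <- bruUpdate(img, tinySeg, tinyStimulus,
                       remodellingParams(B = 0.25, k = 30))
  expect_identical(imgData(out0), imgData(outBase))
})

test_that("simulation steps are deterministic and clamp is never violated", {
  p <- remodellingParams(B = 0.5, k = 20)
  a <- simulateStep(tinyPhantom, tinySeg, idCal, 20, p, "sed",
                    stimulus = tinyStimulus)
  b <- simulateStep(tinyPhantom, tinySeg, idCal, 20, p, "sed",
                    stimulus = tinyStimulus)
  expect_identical(imgData(a), imgData(b))
  tmd <- greyToTmd(a, idCal)
  expect_true(all(imgData(tmd) >= 0 & imgData(tmd) <= 1400))
  # a stimulus node set that is not the current surface is rejected
  wrongMask <- BoneMask(imgData(tinyMask)[, , c(2:dim(tinyMask)[3], 1)],
                        spacing(tinyMask))
  stWrong <- surfaceStimulusField(wrongMask, 1, "sed")
  expect_error(bruUpdate(greyToTmd(tinyPhantom, idCal), tinySeg, stWrong,
                         p), "surface")
})
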