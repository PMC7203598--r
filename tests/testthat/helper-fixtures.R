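# Shared fixtures, built once per test run. All synthetic; nothing on disk.

# identity calibration: grey values equal TMD (mg/cc)
idCal <- densitometricCalibration()

# small tapered-tube phantom used wherever a full FE solve is needed
tinySpec <- phantomSpec(dims = c(26, 26, 40), outerRadius = c(9, 8),
                        wallThickness = c(3, 3), seed = 7L)
tinyPhantom <- makePhantom(tinySpec, idCal)
tinySeg <- segmentImage(tinyPhantom)
tinyMask <- largestComponent(binarise(tinyPhantom, tinySeg@threshold))

# elastic solution of the tiny phantom under the default physiological load
# (computed once; the SED field drives most remodelling tests)
tinyStimulus <- BoneAdapt:::.stimulusForImage(tinyPhantom, tinySeg, 20, "sed")

# a clean two-value phantom (no blur, no noise) for exact-geometry checks
cleanSpec <- phantomSpec(dims = c(24, 24, 30), outerRadius = c(8, 7),
                         wallThickness = c(3, 3), boneTmd = c(900, 0),
                         backgroundTmd = c(100, 0), blurSigma = 0, seed = 1L)
cleanPhantom <- makePhantom(cleanSpec, idCal)

# brute-force reference: 3D face-connected labelling by repeated dilation
refLabelComponents <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  nextLab <- 0L
  idx <- which(m)
  for (s in idx) {
    if (lab[s] != 0L) next
    nextLab <- nextLab + 1L
    frontier <- s
    lab[s] <- nextLab
    while (length(frontier) > 0) {
      k <- (frontier - 1L) %/% (d[1] * d[2])
      r <- (frontier - 1L) %% (d[1] * d[2])
      j <- r %/% d[1]; i <- r %% d[1]
      nb <- integer(0)
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
        ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
        nb <- c(nb, (ii + d[1] * (jj + d[2] * kk) + 1L)[ok])
      }
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- nextLab
      frontier <- unique(nb)
    }
  }
  lab
}

# brute-force transition-zone scan: nearest bin with count >= 2x the
# threshold-bin count, outward on each side
refTransitionZone <- function(mids, counts, threshold) {
  it <- which.min(abs(mids - threshold))
  need <- 2 * counts[it]
  low <- NA
  for (i in rev(seq_len(it - 1))) if (counts[i] >= need) { low <- mids[i]; break }
  high <- NA
  for (i in seq(it + 1, length.out = length(mids) - it))
    if (counts[i] >= need) { high <- mids[i]; break }
  c(low = low, high = high)
}

expectVoxelEqual <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(imgData(a), imgData(b))
  else expect_lt(max(abs(imgData(a) - imgData(b))), tol)
}
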