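#' @include calibration.R
NULL

# ideal tube mask for a PhantomSpec: tapered hollow cylinder along z
.phantomTube <- function(spec) {
  d <- spec@dims
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  m <- array(FALSE, d)
  x <- seq_len(d[1]) - 0.5
  y <- seq_len(d[2]) - 0.5
  for (k in seq_len(d[3])) {
    t <- if (d[3] > 1) (k - 1) / (d[3] - 1) else 0
    rOut <- spec@outerRadius[1] + t * diff(spec@outerRadius)
    wall <- spec@wallThickness[1] + t * diff(spec@wallThickness)
    rIn <- rOut - wall
    r2out <- outer((x - cx)^2, (y - cy)^2, `+`)
    r2in <- outer((x - cx - spec@lumenOffset[1])^2,
                  (y - cy - spec@lumenOffset[2])^2, `+`)
    m[, , k] <- r2out <= rOut^2 & r2in > rIn^2
  }
  m
}

#' Generate a tibia-like phantom image
#'
#' Voxelises a tapered hollow tube (long axis = z, proximal at max z),
#' assigns Gaussian-jittered bone and background TMD values, applies a
#' Gaussian surface blur emulating the partial volume effect, and converts
#' TMD to grey values with the supplied calibration. Deterministic for a
#' fixed spec (the seed lives in the spec); the grey histogram is bimodal by
#' construction.
#'
#' @param spec a [PhantomSpec-class].
#' @param cal a [DensitometricCalibration-class] (identity by default, so
#'   grey values equal TMD).
#' @return A grey-value [VoxelImage-class].
#' @export
makePhantom <- function(spec, cal = densitometricCalibration()) {
  validObject(spec)
  tube <- .phantomTube(spec)
  d <- spec@dims
  ideal <- array(spec@backgroundTmd[1], d)
  ideal[tube] <- spec@boneTmd[1]
  blurred <- array(.blur3d(as.vector(ideal), d, spec@blurSigma), d)
  tmd <- withSeed(spec@seed, {
    sdMap <- array(spec@backgroundTmd[2], d)
    sdMap[tube] <- spec@boneTmd[2]
    blurred + array(rnorm(prod(d)), d) * sdMap
  })
  tmd <- pmax(tmd, 0)
  img <- tmdToGrey(VoxelImage(tmd, spec@spacing, "mg/cc"), cal)
  img
}

#' Ideal bone mask of a phantom
#'
#' The exact voxelised tube geometry of a spec, before blur and noise; the
#' ground truth for segmentation and morphometry oracles.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [BoneMask-class].
#' @export
phantomMask <- function(spec) {
  BoneMask(.phantomTube(spec), spec@spacing)
}

#' Forward-simulate a follow-up image with known parameters
#'
#' One remodelling step with known `(B*, k*)`; the returned image is the
#' ground-truth target for parameter-recovery experiments in
#' [calibrate()].
#'
#' @param baseline a grey-value [VoxelImage-class].
#' @param seg a [SegmentationModel-class].
#' @param cal a [DensitometricCalibration-class].
#' @param bodyMass grams.
#' @param trueParams the generating [RemodellingParams-class].
#' @param kind stimulus kind.
#' @return the follow-up grey-value [VoxelImage-class].
#' @export
forwardFollowUp <- function(baseline, seg, cal, bodyMass, trueParams,
                            kind = c("sed", "maxprinc")) {
  simulateStep(baseline, seg, cal, bodyMass, trueParams, kind)
}

#' Canonical fixture masks
#'
#' Simple geometries with closed-form mechanical and morphometric
#' properties: a full-grid `bar`/`plate`/`cube`, or an `annulus` (hollow
#' circular prism; bone where `inner < r <= outer` from the grid centre,
#' voxel-centre sampling).
#'
#' @param kind `"bar"`, `"plate"`, `"cube"` or `"annulus"`.
#' @param dims grid dimensions (the solid kinds fill the grid).
#' @param outer,inner annulus radii in voxels.
#' @param spacing voxel edge length, micrometres.
#' @return A [BoneMask-class].
#' @export
makeFixture <- function(kind = c("bar", "plate", "cube", "annulus"), dims,
                        outer = NULL, inner = NULL, spacing = 40) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  stopifnot(all(dims >= 1))
  if (kind == "annulus") {
    if (is.null(outer) || is.null(inner))
      stop("annulus requires `outer` and `inner` radii")
    cx <- (dims[1] + 1) / 2
    cy <- (dims[2] + 1) / 2
    x <- seq_len(dims[1]) - 0.5
    y <- seq_len(dims[2]) - 0.5
    r2 <- outer((x - cx)^2, (y - cy)^2, `+`)
    sl <- r2 <= outer^2 & r2 > inner^2
    m <- array(sl, dims)
  } else {
    m <- array(TRUE, dims)
  }
  BoneMask(m, spacing)
}
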