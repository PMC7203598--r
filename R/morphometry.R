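#' @include remodelling.R
NULL

.sectorLabels <- c("anterior", "posterior", "medial", "lateral")

#' Build the compartment atlas
#'
#' Splits the occupied longitudinal extent of the mask into `nSections`
#' equal-length bands (integer-division remainder slices assigned to the
#' most proximal band), numbered 1 (distal) to `nSections` (proximal), and
#' assigns each voxel an angular sector about the whole-bone bone-centroid
#' axis with quadrant boundaries at the 45-degree diagonals: anterior = +y,
#' posterior = -y, medial = +x, lateral = -x. Boundaries are half-open,
#' rotating consistently (a voxel exactly on a diagonal joins the sector
#' counter-clockwise of it), so axisymmetric geometries split evenly.
#'
#' @param mask a [BoneMask-class].
#' @param nSections number of longitudinal sections (default 10).
#' @return A [CompartmentAtlas-class].
#' @export
buildAtlas <- function(mask, nSections = 10) {
  m <- mask@mask
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  occ <- which(apply(m, 3, any))
  z0 <- min(occ); z1 <- max(occ)
  nSlices <- z1 - z0 + 1L
  base <- nSlices %/% nSections
  if (base < 1L) stop("more sections than occupied slices")
  sizes <- rep(base, nSections)
  sizes[nSections] <- sizes[nSections] + nSlices %% nSections
  secOfSlice <- rep(seq_len(nSections), times = sizes)
  section <- array(0L, d)
  for (k in seq_len(nSlices))
    section[, , z0 + k - 1L] <- secOfSlice[k]
  ctr <- .maskCentroid(m)[1:2]
  dx <- (seq_len(d[1]) - ctr[1])
  dy <- (seq_len(d[2]) - ctr[2])
  DX <- array(rep(dx, times = d[2] * d[3]), d)
  DY <- array(rep(rep(dy, each = d[1]), times = d[3]), d)
  ang <- atan2(DY, DX)
  sector <- array(0L, d)
  sector[ang >= -pi / 4 & ang < pi / 4] <- 3L              # medial  (+x)
  sector[ang >= pi / 4 & ang < 3 * pi / 4] <- 1L           # anterior (+y)
  sector[ang >= 3 * pi / 4 | ang < -3 * pi / 4] <- 4L      # lateral (-x)
  sector[ang >= -3 * pi / 4 & ang < -pi / 4] <- 2L         # posterior (-y)
  new("CompartmentAtlas", section = section, sector = sector,
      nSections = as.integer(nSections), spacing = mask@spacing)
}

#' Sectional volumetric second moments
#'
#' Per section, `Ixx = sum (y - ybar)^2 * v` and `Iyy = sum (x - xbar)^2 *
#' v` over the section's bone voxels, with voxel-centre coordinates, voxel
#' volume `v` and the section's own bone centroid `(xbar, ybar)` as the
#' reference (making the profile insensitive to residual in-plane
#' translation). Units: mm^5.
#'
#' @param mask a [BoneMask-class].
#' @param atlas the matching [CompartmentAtlas-class].
#' @return A [SecondMomentProfile-class].
#' @export
volumetricSecondMoments <- function(mask, atlas) {
  m <- mask@mask
  if (!identical(dim(m), dim(atlas@section)))
    stop("atlas does not match the mask")
  spMm <- mask@spacing / 1000
  v <- spMm^3
  idx <- which(m, arr.ind = TRUE)
  x <- (idx[, 1] - 0.5) * spMm
  y <- (idx[, 2] - 0.5) * spMm
  sec <- atlas@section[m]
  n <- atlas@nSections
  Ixx <- Iyy <- numeric(n)
  for (s in seq_len(n)) {
    in.s <- sec == s
    if (!any(in.s)) {
      warning("empty section ", s, "; moments set to zero")
      next
    }
    Ixx[s] <- sum((y[in.s] - mean(y[in.s]))^2) * v
    Iyy[s] <- sum((x[in.s] - mean(x[in.s]))^2) * v
  }
  new("SecondMomentProfile", section = seq_len(n), Ixx = Ixx, Iyy = Iyy)
}

#' Periosteal-enclosed mask
#'
#' Bone voxels plus cavity (medullary) voxels not reachable from the image
#' border by slice-wise face-connected background flood fill. An open
#' section whose lumen connects to the exterior contributes no cavity.
#'
#' @param mask a [BoneMask-class].
#' @return A [BoneMask-class] of the enclosed volume.
#' @export
periostealMask <- function(mask) {
  if (!any(mask@mask)) stop("empty mask")
  codes <- array(.flood_exterior_slices(as.vector(mask@mask), dim(mask@mask)),
                 dim(mask@mask))
  BoneMask(codes != 1L, mask@spacing)
}

#' Total volume enclosed by the periosteal surface, per region
#'
#' @param mask a [BoneMask-class].
#' @param atlas optional [CompartmentAtlas-class]; when supplied, TV is
#'   reported per compartment as well as whole-bone.
#' @return data.frame with columns region, section, sector, TV (mm^3).
#' @export
periostealVolume <- function(mask, atlas = NULL) {
  tv <- periostealMask(mask)@mask
  vMm3 <- (mask@spacing / 1000)^3
  out <- data.frame(region = "whole", section = NA_integer_,
                    sector = NA_character_, TV = sum(tv) * vMm3,
                    stringsAsFactors = FALSE)
  if (!is.null(atlas)) {
    for (s in seq_len(atlas@nSections))
      for (q in 1:4) {
        sel <- tv & atlas@section == s & atlas@sector == q
        out <- rbind(out, data.frame(
          region = sprintf("S%02d.%s", s, .sectorLabels[q]),
          section = s, sector = .sectorLabels[q], TV = sum(sel) * vMm3,
          stringsAsFactors = FALSE))
      }
  }
  out
}

#' Densitometric indices per region
#'
#' Bone volume (BV), total periosteal-enclosed volume (TV), BV/TV, bone
#' mineral content (BMC = sum of TMD times voxel volume over bone voxels),
#' volumetric bone mineral density (BMD = BMC / TV) and mean TMD, for the
#' whole bone and each of the atlas compartments. Regions with TV = 0 report
#' BMD as `NA`.
#'
#' @param image a [VoxelImage-class] in mg/cc.
#' @param mask the congruent [BoneMask-class].
#' @param atlas the matching [CompartmentAtlas-class].
#' @return A [DensitometricReport-class].
#' @export
densitometrics <- function(image, mask, atlas) {
  if (image@unit != "mg/cc") stop("densitometrics expects a TMD image (mg/cc)")
  if (!identical(dim(image@data), dim(mask@mask)))
    stop("image and mask dimensions disagree")
  spMm <- mask@spacing / 1000
  vMm3 <- spMm^3
  vCc <- vMm3 / 1000
  tvMask <- periostealMask(mask)@mask
  m <- mask@mask
  tmd <- image@data
  regionRow <- function(region, s, q, sel, selTv) {
    bv <- sum(sel) * vMm3
    tv <- sum(selTv) * vMm3
    bmc <- sum(tmd[sel]) * vCc
    data.frame(region = region, section = s, sector = q,
               BV = bv, TV = tv, BVTV = if (tv > 0) bv / tv else NA_real_,
               BMC = bmc,
               BMD = if (tv > 0) bmc / (tv / 1000) else NA_real_,
               meanTMD = if (any(sel)) mean(tmd[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list(regionRow("whole", NA_integer_, NA_character_, m, tvMask))
  for (s in seq_len(atlas@nSections))
    for (q in 1:4) {
      inReg <- atlas@section == s & atlas@sector == q
      rows[[length(rows) + 1L]] <- regionRow(
        sprintf("S%02d.%s", s, .sectorLabels[q]), s, .sectorLabels[q],
        m & inReg, tvMask & inReg)
    }
  new("DensitometricReport", table = do.call(rbind, rows))
}

#' Percentage error between predicted and experimental reports
#'
#' `100 * (predicted - experimental) / experimental` per index per region;
#' positive values are over-predictions. Entries with a zero experimental
#' value are `NA`.
#'
#' @param pred,exp [DensitometricReport-class]s with matching regions.
#' @return data.frame of percentage errors per region.
#' @export
percentError <- function(pred, exp) {
  p <- pred@table
  e <- exp@table
  if (!identical(p$region, e$region))
    stop("reports have different region structure")
  idx <- c("BV", "TV", "BVTV", "BMC", "BMD", "meanTMD")
  out <- p[, c("region", "section", "sector")]
  for (ix in idx) {
    denom <- e[[ix]]
    err <- 100 * (p[[ix]] - denom) / denom
    err[!is.na(denom) & denom == 0] <- NA_real_
    out[[ix]] <- err
  }
  out
}
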