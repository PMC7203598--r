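#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# image I/O: MetaImage (MHD/RAW), NIfTI-1 and multi-page TIFF stacks.
# Header spacings are in mm (the convention of both formats); VoxelImage
# spacing is micrometres.

.mhdTypes <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
.mhdSizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

.readMhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, function(x) if (length(x)) x[2] else NA_character_, "")
  vals <- vapply(kv, function(x) if (length(x)) trimws(x[3]) else NA_character_, "")
  h <- setNames(vals[!is.na(keys)], keys[!is.na(keys)])
  if (is.na(h["NDims"]) || as.integer(h["NDims"]) != 3L)
    stop("MHD: only 3D volumes are supported")
  dims <- as.integer(strsplit(h[["DimSize"]], "\\s+")[[1]])
  if (is.na(h["ElementSpacing"]))
    stop("MHD: missing ElementSpacing (voxel size)")
  sp <- as.numeric(strsplit(h[["ElementSpacing"]], "\\s+")[[1]])
  if (length(sp) == 1L) sp <- rep(sp, 3)
  if (max(sp) - min(sp) > 1e-9 * max(sp))
    stop("anisotropic voxel spacing is not supported")
  type <- h[["ElementType"]]
  if (!type %in% names(.mhdTypes)) stop("MHD: unsupported ElementType ", type)
  msb <- identical(h["BinaryDataByteOrderMSB"], c(BinaryDataByteOrderMSB = "True")) ||
         identical(h["ElementByteOrderMSB"], c(ElementByteOrderMSB = "True"))
  raw <- h[["ElementDataFile"]]
  if (identical(raw, "LOCAL")) stop("MHD: embedded data not supported")
  rawPath <- file.path(dirname(path), raw)
  if (!file.exists(rawPath)) stop("MHD: raw file not found: ", rawPath)
  n <- prod(dims)
  con <- file(rawPath, "rb")
  on.exit(close(con))
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  v <- readBin(con, what = .mhdTypes[[type]], n = n,
               size = .mhdSizes[[type]], signed = signed,
               endian = if (msb) "big" else "little")
  if (length(v) != n) stop("MHD: raw file shorter than DimSize promises")
  VoxelImage(array(as.double(v), dims), spacing = sp[1] * 1000)
}

.writeMhd <- function(image, path) {
  rawName <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(image@data)
  spMm <- image@spacing / 1000
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(rep(format(spMm, digits = 15), 3),
                                           collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", rawName))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawName), "wb")
  on.exit(close(con))
  writeBin(as.double(as.vector(image@data)), con, size = 8L,
           endian = "little")
  invisible(path)
}

.readNiftiImage <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(dim(img)) != 3L) stop("NIfTI: only 3D volumes are supported")
  if (max(pd[1:3]) - min(pd[1:3]) > 1e-9 * max(pd[1:3]))
    stop("anisotropic voxel spacing is not supported")
  VoxelImage(array(as.double(img), dim(img)), spacing = pd[1] * 1000)
}

.writeNiftiImage <- function(image, path) {
  nii <- RNifti::asNifti(image@data)
  RNifti::pixdim(nii) <- rep(image@spacing / 1000, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# TIFF stacks carry no spacing metadata; values must be integers in
# [0, 65535] and are stored as 16-bit samples.
.readTiffStack <- function(path, spacing = NULL) {
  if (is.null(spacing))
    stop("TIFF stacks carry no voxel size; supply `spacing` explicitly")
  sl <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(sl)) sl <- list(sl)
  d <- dim(sl[[1]])
  arr <- array(0, c(d[1], d[2], length(sl)))
  for (k in seq_along(sl)) arr[, , k] <- round(sl[[k]] * 65535)
  VoxelImage(arr, spacing = spacing)
}

.writeTiffStack <- function(image, path) {
  v <- image@data
  if (any(v < 0 | v > 65535) || any(abs(v - round(v)) > 1e-9))
    stop("TIFF export requires integer grey values in [0, 65535]")
  sl <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / 65535)
  tiff::writeTIFF(sl, path, bits.per.sample = 16L)
  invisible(path)
}

.guessFormat <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(ext, mhd = "mhd", nii = "nifti", tif = "tiff", tiff = "tiff",
         stop("cannot guess image format from extension: ", path))
}

#' Read a voxel image
#'
#' Supported formats: MetaImage (`.mhd` + little-endian `.raw`), NIfTI-1
#' (`.nii`, `.nii.gz`) and multi-page TIFF stacks. Header spacings are
#' interpreted as mm and converted to micrometres. TIFF stacks carry no
#' spacing, so `spacing` must be supplied for them; for the other formats it
#' overrides the header when given.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"mhd"`, `"nifti"`, `"tiff"`.
#' @param spacing voxel edge length override, micrometres.
#' @return A [VoxelImage-class].
#' @export
readVoxelImage <- function(path, format = c("auto", "mhd", "nifti", "tiff"),
                           spacing = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guessFormat(path)
  img <- switch(format,
    mhd = .readMhd(path),
    nifti = .readNiftiImage(path),
    tiff = .readTiffStack(path, spacing))
  if (!is.null(spacing)) img@spacing <- spacing
  validObject(img)
  img
}

#' Write a voxel image
#'
#' @param image a [VoxelImage-class].
#' @param path output path; format chosen by extension unless given.
#' @param format one of `"auto"`, `"mhd"`, `"nifti"`, `"tiff"`.
#' @return the path, invisibly.
#' @export
writeVoxelImage <- function(image, path,
                            format = c("auto", "mhd", "nifti", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  switch(format,
    mhd = .writeMhd(image, path),
    nifti = .writeNiftiImage(image, path),
    tiff = .writeTiffStack(image, path))
}

# ---------------------------------------------------------------------------
# densitometric calibration

#' Convert grey values to tissue mineral density
#'
#' Applies the linear densitometric calibration `tmd = slope * grey +
#' intercept` voxel-wise. [tmdToGrey()] is the exact inverse.
#'
#' @param image a [VoxelImage-class] in grey units.
#' @param cal a [DensitometricCalibration-class].
#' @return A [VoxelImage-class] in mg/cc.
#' @export
greyToTmd <- function(image, cal) {
  VoxelImage(cal@slope * image@data + cal@intercept, image@spacing,
             unit = "mg/cc")
}

#' @rdname greyToTmd
#' @export
tmdToGrey <- function(image, cal) {
  VoxelImage((image@data - cal@intercept) / cal@slope, image@spacing,
             unit = "grey")
}

# ---------------------------------------------------------------------------
# histogram, threshold, transition zone

#' Grey-value histogram of an image
#'
#' For integer-valued data the default bin width is 1 grey unit (bins centred
#' on the integers); otherwise a Freedman--Diaconis-style width is used.
#'
#' @param image a [VoxelImage-class].
#' @param binWidth bin width in grey units, or `NULL` for the default rule.
#' @return A [GreyHistogram-class].
#' @export
greyHistogram <- function(image, binWidth = NULL) {
  v <- as.vector(image@data)
  if (is.null(binWidth)) {
    if (all(abs(v - round(v)) < 1e-9)) {
      binWidth <- 1
    } else {
      iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE))
      binWidth <- max(2 * iqr / length(v)^(1 / 3), diff(range(v)) / 512)
      if (binWidth <= 0) binWidth <- 1
    }
  }
  lo <- floor(min(v) / binWidth) * binWidth - binWidth / 2
  nb <- ceiling((max(v) - lo) / binWidth) + 1L
  breaks <- lo + (0:nb) * binWidth
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = nb)
  new("GreyHistogram", mids = (breaks[-1] + breaks[-(nb + 1)]) / 2,
      counts = as.numeric(counts), binWidth = binWidth)
}

# local maxima of a count vector; plateaus collapse to their lowest-grey bin
.localMaxima <- function(counts) {
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (m in seq_along(r$values)) {
    left <- if (m == 1L) -Inf else r$values[m - 1L]
    right <- if (m == length(r$values)) -Inf else r$values[m + 1L]
    if (r$values[m] > left && r$values[m] > right) out <- c(out, starts[m])
  }
  out
}

#' Bone/background threshold from a bimodal histogram
#'
#' The threshold is the midpoint between the background and bone histogram
#' peaks. The background peak is the dominant mode; the bone peak is the
#' local maximum with the greatest prominence relative to the valley
#' separating it from the dominant mode, which makes the rule robust to
#' counting noise riding on the two humps. Ties are broken towards lower
#' grey values, and the result is invariant under rescaling of the counts
#' by any positive constant.
#'
#' @param hist a [GreyHistogram-class].
#' @return threshold in grey units.
#' @export
computeThreshold <- function(hist) {
  cnt <- hist@counts
  pk <- .localMaxima(cnt)
  if (length(pk) < 2L)
    stop("segmentation failure: histogram is not bimodal (",
         length(pk), " mode(s) found)")
  p1 <- pk[which.max(cnt[pk])]
  cand <- setdiff(pk, p1)
  prom <- vapply(cand, function(p) {
    lo <- min(p, p1) + 1L; hi <- max(p, p1) - 1L
    valley <- if (lo > hi) min(cnt[p], cnt[p1]) else min(cnt[lo:hi])
    min(cnt[p], cnt[p1]) - valley
  }, numeric(1))
  if (max(prom) <= 0)
    stop("segmentation failure: no second mode separated by a valley")
  p2 <- cand[which.max(prom)]
  (hist@mids[p1] + hist@mids[p2]) / 2
}

#' Transition zone around a threshold
#'
#' Scanning outward from the threshold bin, the transition-zone bounds are
#' the nearest bins below and above whose count is at least twice the count
#' of the threshold bin (the onset of the background and bone grey-value
#' populations). A side with no qualifying bin is set to the histogram
#' extreme with a warning.
#'
#' @param hist a [GreyHistogram-class].
#' @param threshold grey units.
#' @return named numeric `c(tzLow, tzHigh)` in grey units (bin midpoints).
#' @export
computeTransitionZone <- function(hist, threshold) {
  mids <- hist@mids
  cnt <- hist@counts
  it <- which.min(abs(mids - threshold))
  need <- 2 * cnt[it]
  lowIdx <- rev(seq_len(it - 1L))
  hiIdx <- seq(it + 1L, length.out = max(0L, length(mids) - it))
  lw <- lowIdx[which(cnt[lowIdx] >= need)[1]]
  hg <- hiIdx[which(cnt[hiIdx] >= need)[1]]
  if (is.na(lw)) {
    warning("no qualifying bin below the threshold; using histogram minimum")
    lw <- 1L
  }
  if (is.na(hg)) {
    warning("no qualifying bin above the threshold; using histogram maximum")
    hg <- length(mids)
  }
  c(tzLow = mids[lw], tzHigh = mids[hg])
}

#' Segment an image: threshold plus transition zone
#'
#' Convenience wrapper computing the histogram, the peak-midpoint threshold
#' and the transition zone in one call. The model is intended to be computed
#' once from the baseline scan of a subject and reused at all time points.
#'
#' @param image a [VoxelImage-class] in grey units.
#' @param binWidth histogram bin width, or `NULL` for the default rule.
#' @return A [SegmentationModel-class].
#' @export
segmentImage <- function(image, binWidth = NULL) {
  h <- greyHistogram(image, binWidth)
  thr <- computeThreshold(h)
  tz <- computeTransitionZone(h, thr)
  segmentationModel(thr, tz[["tzLow"]], tz[["tzHigh"]])
}

#' Serialise a segmentation model as plain text
#'
#' @param seg a [SegmentationModel-class].
#' @param path file path.
#' @return the path (write) or a [SegmentationModel-class] (read).
#' @export
writeSegmentationModel <- function(seg, path) {
  writeLines(c("[segmentation]",
               sprintf("threshold = %.15g", seg@threshold),
               sprintf("tz_low = %.15g", seg@tzLow),
               sprintf("tz_high = %.15g", seg@tzHigh)), path)
  invisible(path)
}

#' @rdname writeSegmentationModel
#' @export
readSegmentationModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get1 <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\s*="), lines, value = TRUE)
    if (length(ln) == 0) stop("missing key in segmentation file: ", key)
    as.numeric(sub(".*=\\s*", "", ln[1]))
  }
  segmentationModel(get1("threshold"), get1("tz_low"), get1("tz_high"))
}

# ---------------------------------------------------------------------------
# binarisation, cropping, alignment, components

#' Binarise an image at a threshold
#'
#' A voxel is bone iff its value is strictly greater than the threshold
#' (a voxel exactly at the threshold is background).
#'
#' @param image a [VoxelImage-class].
#' @param threshold same units as the image values.
#' @return A [BoneMask-class].
#' @export
binarise <- function(image, threshold) {
  BoneMask(image@data > threshold, image@spacing)
}

#' Crop to a fraction of the occupied longitudinal extent
#'
#' The occupied extent is the z-slice range containing voxels above the
#' threshold; `floor(fraction * extent)` slices are retained, measured from
#' the chosen end (proximal = maximum z).
#'
#' @param image a [VoxelImage-class].
#' @param fraction in (0, 1].
#' @param from `"proximal"` or `"distal"`.
#' @param threshold occupancy threshold, same units as the image.
#' @return the cropped [VoxelImage-class].
#' @export
cropLongitudinalFraction <- function(image, fraction,
                                     from = c("proximal", "distal"),
                                     threshold) {
  from <- match.arg(from)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  occ <- which(apply(image@data > threshold, 3, any))
  if (length(occ) == 0) stop("no occupied slices above the threshold")
  z0 <- min(occ); z1 <- max(occ)
  keep <- max(1L, floor(fraction * (z1 - z0 + 1L)))
  zr <- if (from == "proximal") (z1 - keep + 1L):z1 else z0:(z0 + keep - 1L)
  VoxelImage(image@data[, , zr, drop = FALSE], image@spacing, image@unit)
}

.maskCentroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  colMeans(idx)
}

.shiftArray <- function(a, shift, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    src[[ax]] <- max(1, 1 - s):min(d[ax], d[ax] - s)
    dst[[ax]] <- src[[ax]] + s
  }
  if (any(vapply(src, length, 1L) == 0)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Align two longitudinal images for comparison
#'
#' Translates the moving image by the integer voxel shift centring the
#' bone-volume centroids (no rotation: the main axis is assumed already
#' registered upstream), then crops both images to the common bounding box of
#' the union of their bone masks so the outputs have identical dimensions.
#'
#' @param reference,moving [VoxelImage-class]s in the same units.
#' @param threshold binarisation threshold.
#' @return list with elements `reference`, `moving` (equal-dimension
#'   [VoxelImage-class]s) and `shift` (integer voxel translation applied).
#' @export
alignForComparison <- function(reference, moving, threshold) {
  mr <- reference@data > threshold
  mm <- moving@data > threshold
  if (!any(mr) || !any(mm)) stop("empty bone mask in one of the images")
  shift <- as.integer(round(.maskCentroid(mr) - .maskCentroid(mm)))
  fill <- min(moving@data)
  movedData <- .shiftArray(moving@data, shift, fill)
  mmv <- movedData > threshold
  un <- mr | mmv
  idx <- which(un, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  sub <- function(a) a[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                       rng[1, 3]:rng[2, 3], drop = FALSE]
  list(reference = VoxelImage(sub(reference@data), reference@spacing,
                              reference@unit),
       moving = VoxelImage(sub(movedData), moving@spacing, moving@unit),
       shift = shift)
}

#' Largest connected component of a mask
#'
#' Retains the single largest connected component (ties broken towards the
#' lowest component label, i.e. the first encountered in scan order). The
#' finite-element solver requires a single face-connected component with no
#' floating elements.
#'
#' @param mask a [BoneMask-class].
#' @param connectivity `"face"`, `"edge"` or `"vertex"`.
#' @return A [BoneMask-class].
#' @export
largestComponent <- function(mask, connectivity = c("face", "edge", "vertex")) {
  connectivity <- match.arg(connectivity)
  if (!any(mask@mask)) stop("empty mask")
  conn <- match(connectivity, c("face", "edge", "vertex"))
  lab <- .cc_label3d(as.vector(mask@mask), dim(mask@mask), conn)
  ncomp <- attr(lab, "ncomp")
  if (ncomp == 1L) return(mask)
  sizes <- tabulate(lab, nbins = ncomp)
  keep <- which.max(sizes)
  BoneMask(array(lab == keep, dim(mask@mask)), mask@spacing)
}

#' Number of connected components of a mask
#' @inheritParams largestComponent
#' @return integer component count.
#' @export
countComponents <- function(mask, connectivity = c("face", "edge", "vertex")) {
  connectivity <- match.arg(connectivity)
  conn <- match(connectivity, c("face", "edge", "vertex"))
  lab <- .cc_label3d(as.vector(mask@mask), dim(mask@mask), conn)
  attr(lab, "ncomp")
}
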