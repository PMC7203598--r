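#' @include morphometry.R
NULL

#' Overlap ratio (Jaccard) of two bone masks
#'
#' Intersection over union of the bone voxels; 1 iff the masks are
#' identical, 0 for disjoint masks. Align the images first (see
#' [alignForComparison()]).
#'
#' @param a,b equal-dimension [BoneMask-class]s.
#' @return overlap ratio in `[0, 1]`.
#' @export
overlapRatio <- function(a, b) {
  if (!identical(dim(a@mask), dim(b@mask)))
    stop("masks have different dimensions; align the images first")
  un <- sum(a@mask | b@mask)
  if (un == 0) stop("overlap ratio undefined: both masks are empty")
  sum(a@mask & b@mask) / un
}

# face-neighbour dilation of a logical array
.faceDilate <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Classify bone surface voxels as endosteal or periosteal
#'
#' Background voxels reachable from the image border by slice-wise
#' face-connected flood fill define the exterior. Bone voxels facing the
#' exterior are periosteal; bone voxels facing only enclosed cavities are
#' endosteal (a voxel facing both is counted periosteal). Non-surface
#' voxels are 0.
#'
#' @param mask a [BoneMask-class].
#' @return integer array, same dimensions: 0 none, 1 periosteal,
#'   2 endosteal.
#' @export
classifySurfaces <- function(mask) {
  if (!any(mask@mask)) stop("empty mask")
  m <- mask@mask
  codes <- array(.flood_exterior_slices(as.vector(m), dim(m)), dim(m))
  nearExterior <- .faceDilate(codes == 1L)
  nearCavity <- .faceDilate(codes == 2L)
  out <- array(0L, dim(m))
  out[m & nearExterior] <- 1L
  out[m & !nearExterior & nearCavity] <- 2L
  out
}

#' Remodelling sites between two aligned images
#'
#' On the surface shell of the earlier mask (bone voxels facing background
#' plus background voxels facing bone), a voxel is an apposition site when
#' its grey value crosses the bone threshold upward between the two time
#' points (background to bone) and a resorption site when it crosses
#' downward. Each site is labelled endosteal or periosteal from the earlier
#' mask's surface classification.
#'
#' @param earlier,later aligned equal-dimension grey-value
#'   [VoxelImage-class]s.
#' @param seg a [SegmentationModel-class].
#' @param provenance free-text label stored with the map (e.g.
#'   `"experimental pair"`).
#' @return A [RemodellingSiteMap-class].
#' @export
remodellingSites <- function(earlier, later, seg,
                             provenance = "experimental pair") {
  if (!identical(dim(earlier@data), dim(later@data)))
    stop("images are misaligned (different dimensions)")
  thr <- seg@threshold
  m0 <- earlier@data > thr
  m1 <- later@data > thr
  boneShell <- m0 & .faceDilate(!m0)
  bgShell <- !m0 & .faceDilate(m0)
  app <- which(bgShell & m1)
  res <- which(boneShell & !m1)
  codes <- array(.flood_exterior_slices(as.vector(m0), dim(m0)), dim(m0))
  surfClass <- classifySurfaces(BoneMask(m0, earlier@spacing))
  labelOf <- function(ix, isBone) {
    if (length(ix) == 0) return(character(0))
    if (isBone) {
      ifelse(surfClass[ix] == 2L, "endosteal", "periosteal")
    } else {
      ifelse(codes[ix] == 2L, "endosteal", "periosteal")
    }
  }
  sites <- rbind(
    data.frame(index = app, direction = rep("apposition", length(app)),
               surface = labelOf(app, FALSE), stringsAsFactors = FALSE),
    data.frame(index = res, direction = rep("resorption", length(res)),
               surface = labelOf(res, TRUE), stringsAsFactors = FALSE))
  new("RemodellingSiteMap", sites = sites, dims = dim(earlier@data),
      provenance = provenance)
}

#' Spatial match and prediction accuracy of remodelling predictions
#'
#' For each remodelling direction, surface class and longitudinal section
#' (plus pooled totals), the correctly predicted sites are the intersection
#' of the predicted and experimental site sets. Spatial match =
#' `100 * |correct| / |predicted|`; prediction accuracy =
#' `100 * |correct| / |experimental|`. Entries with an empty denominator are
#' `NA`. Whole-bone values pool sites rather than averaging sections.
#'
#' @param predicted,experimental [RemodellingSiteMap-class]s from congruent
#'   image pairs.
#' @param atlas optional [CompartmentAtlas-class] for the per-section
#'   breakdown.
#' @return data.frame with columns direction, surface, section,
#'   nPredicted, nExperimental, nCorrect, spatialMatch, accuracy.
#' @export
matchMetrics <- function(predicted, experimental, atlas = NULL) {
  if (!identical(predicted@dims, experimental@dims))
    stop("site maps come from different image geometries")
  p <- predicted@sites
  e <- experimental@sites
  sections <- if (is.null(atlas)) integer(0) else seq_len(atlas@nSections)
  secOf <- function(ix) {
    if (is.null(atlas)) return(rep(NA_integer_, length(ix)))
    atlas@section[ix]
  }
  p$sec <- secOf(p$index)
  e$sec <- secOf(e$index)
  rows <- list()
  for (dir in c("apposition", "resorption"))
    for (surf in c("all", "endosteal", "periosteal")) {
      ps <- p[p$direction == dir & (surf == "all" | p$surface == surf), ]
      es <- e[e$direction == dir & (surf == "all" | e$surface == surf), ]
      for (s in c(NA_integer_, sections)) {
        pix <- if (is.na(s)) ps$index else ps$index[ps$sec %in% s]
        eix <- if (is.na(s)) es$index else es$index[es$sec %in% s]
        nc <- length(intersect(pix, eix))
        rows[[length(rows) + 1L]] <- data.frame(
          direction = dir, surface = surf, section = s,
          nPredicted = length(pix), nExperimental = length(eix),
          nCorrect = nc,
          spatialMatch = if (length(pix) > 0) 100 * nc / length(pix)
                         else NA_real_,
          accuracy = if (length(eix) > 0) 100 * nc / length(eix)
                     else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  do.call(rbind, rows)
}
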