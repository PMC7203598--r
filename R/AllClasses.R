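#' @include BoneAdapt-package.R
NULL

#' Grey-value voxel volume
#'
#' A 3D scalar grid with isotropic voxel spacing. Axis convention:
#' x = medial--lateral, y = anterior--posterior, z = longitudinal with the
#' proximal end at maximum z. The unit flag records whether voxel values are
#' raw scanner grey values (`"grey"`) or calibrated tissue mineral density in
#' mg/cc (`"mg/cc"`).
#'
#' @slot data numeric 3D array of voxel values.
#' @slot spacing isotropic voxel edge length, micrometres.
#' @slot unit `"grey"` or `"mg/cc"`.
#' @export
setClass("VoxelImage",
  representation(data = "array", spacing = "numeric", unit = "character"),
  prototype(spacing = 10.4, unit = "grey"))

setValidity("VoxelImage", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (any(dim(d) < 1L)) return("all three dimensions must be >= 1")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0) return("spacing must be a single positive number")
  if (!all(is.finite(d))) return("voxel values must be finite")
  if (!object@unit %in% c("grey", "mg/cc"))
    return("unit must be 'grey' or 'mg/cc'")
  TRUE
})

#' Construct a VoxelImage
#'
#' @param data numeric 3D array.
#' @param spacing voxel edge length in micrometres (isotropic).
#' @param unit `"grey"` (raw values) or `"mg/cc"` (calibrated TMD).
#' @return A [VoxelImage-class] object.
#' @examples
#' img <- VoxelImage(array(0, c(5, 5, 5)), spacing = 10.4)
#' dim(img)
#' @export
VoxelImage <- function(data, spacing = 10.4, unit = "grey") {
  storage.mode(data) <- "double"
  new("VoxelImage", data = data, spacing = spacing, unit = unit)
}

#' Densitometric calibration
#'
#' Linear grey-to-TMD map `tmd = slope * grey + intercept`, as provided by a
#' CT manufacturer for a given scan protocol.
#'
#' @slot slope mg/cc per grey unit (> 0).
#' @slot intercept mg/cc.
#' @export
setClass("DensitometricCalibration",
  representation(slope = "numeric", intercept = "numeric"),
  prototype(slope = 1, intercept = 0))

setValidity("DensitometricCalibration", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0) return("slope must be a single positive number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  TRUE
})

#' @param slope mg/cc per grey unit.
#' @param intercept mg/cc.
#' @rdname DensitometricCalibration-class
#' @export
densitometricCalibration <- function(slope = 1, intercept = 0) {
  new("DensitometricCalibration", slope = slope, intercept = intercept)
}

#' Grey-value histogram
#'
#' @slot mids bin midpoints, grey units.
#' @slot counts voxel counts per bin.
#' @slot binWidth bin width, grey units.
#' @export
setClass("GreyHistogram",
  representation(mids = "numeric", counts = "numeric", binWidth = "numeric"))

setValidity("GreyHistogram", function(object) {
  if (length(object@mids) != length(object@counts))
    return("mids and counts must have equal length")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (object@binWidth <= 0) return("binWidth must be positive")
  TRUE
})

#' Segmentation model: threshold and transition zone
#'
#' The single-level bone/background threshold (midpoint between the
#' background and bone histogram peaks) together with the transition-zone
#' bounds, all in grey units. Voxels with grey values inside
#' `[tzLow, tzHigh]` may represent either bone or background (partial volume
#' effect) and are allowed to remodel in both directions.
#'
#' @slot threshold grey units.
#' @slot tzLow lower transition-zone bound, grey units.
#' @slot tzHigh upper transition-zone bound, grey units.
#' @export
setClass("SegmentationModel",
  representation(threshold = "numeric", tzLow = "numeric", tzHigh = "numeric"))

setValidity("SegmentationModel", function(object) {
  if (!(object@tzLow <= object@threshold && object@threshold <= object@tzHigh))
    return("must satisfy tzLow <= threshold <= tzHigh")
  TRUE
})

#' @param threshold,tzLow,tzHigh grey-value bounds.
#' @rdname SegmentationModel-class
#' @export
segmentationModel <- function(threshold, tzLow = threshold, tzHigh = threshold) {
  new("SegmentationModel", threshold = threshold, tzLow = tzLow,
      tzHigh = tzHigh)
}

#' Binary bone mask
#'
#' @slot mask logical 3D array, `TRUE` = bone.
#' @slot spacing voxel edge length, micrometres.
#' @export
setClass("BoneMask",
  representation(mask = "array", spacing = "numeric"))

setValidity("BoneMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@spacing <= 0) return("spacing must be positive")
  TRUE
})

#' @param mask logical 3D array.
#' @param spacing voxel edge length, micrometres.
#' @rdname BoneMask-class
#' @export
BoneMask <- function(mask, spacing) {
  storage.mode(mask) <- "logical"
  new("BoneMask", mask = mask, spacing = spacing)
}

#' Voxel micro-finite-element model
#'
#' One linear 8-node hexahedral element per bone voxel, homogeneous isotropic
#' material. Nodes on the proximal (max z) boundary layer are fully
#' constrained; nodes on the distal (min z) layer are kinematically coupled
#' to a rotation-fixed reference point at the distal area centroid, at which
#' loads are applied.
#'
#' @slot elems integer matrix (elements x 8), 0-based node indices in the
#'   local ordering used by the element stiffness matrix.
#' @slot nodeIJK integer matrix (nodes x 3), 0-based node-lattice coordinates.
#' @slot nodeType integer per node: 0 free, 1 fixed (proximal), 2 coupled
#'   (distal).
#' @slot voxIJK integer matrix (elements x 3), 0-based voxel coordinates.
#' @slot dims voxel grid dimensions of the source mask.
#' @slot spacing voxel edge length, micrometres.
#' @slot E elastic modulus, Pa.
#' @slot nu Poisson ratio.
#' @slot ke shared 24x24 element stiffness matrix (SI units).
#' @slot refPoint distal reference point (area centroid of the distal
#'   surface), metres.
#' @export
setClass("FEModel",
  representation(elems = "matrix", nodeIJK = "matrix", nodeType = "integer",
                 voxIJK = "matrix", dims = "integer", spacing = "numeric",
                 E = "numeric", nu = "numeric", ke = "matrix",
                 refPoint = "numeric"))

setValidity("FEModel", function(object) {
  if (object@E <= 0) return("E must be positive")
  if (object@nu <= -1 || object@nu >= 0.5) return("nu must be in (-1, 0.5)")
  if (any(object@nodeType != 0L)) { # constraints assigned
    if (!any(object@nodeType == 1L))
      return("empty proximal (fixed) node set")
    if (!any(object@nodeType == 2L))
      return("empty distal (coupled) node set")
  }
  TRUE
})

#' Nodal displacement field
#'
#' @slot values numeric matrix (nodes x 3), metres.
#' @slot load the load vector that produced the field, Newtons (ml, ap, si).
#' @slot iters,relres solver iteration count and final relative residual.
#' @export
setClass("DisplacementField",
  representation(values = "matrix", load = "numeric", iters = "integer",
                 relres = "numeric"))

#' Per-surface-node mechanical stimulus
#'
#' @slot kind `"sed"` (strain energy density, Pa) or `"maxprinc"` (maximum
#'   principal strain, microstrain).
#' @slot values stimulus at each surface node.
#' @slot nodeIJK integer matrix (surface nodes x 3), 0-based node-lattice
#'   coordinates.
#' @slot dims voxel grid dimensions of the source mask.
#' @slot spacing voxel edge length, micrometres.
#' @export
setClass("StimulusField",
  representation(kind = "character", values = "numeric", nodeIJK = "matrix",
                 dims = "integer", spacing = "numeric"))

setValidity("StimulusField", function(object) {
  if (!object@kind %in% c("sed", "maxprinc"))
    return("kind must be 'sed' or 'maxprinc'")
  if (nrow(object@nodeIJK) != length(object@values))
    return("values and nodeIJK disagree in length")
  if (!all(is.finite(object@values))) return("stimulus values must be finite")
  if (object@kind == "sed" && any(object@values < 0))
    return("SED must be non-negative")
  TRUE
})

#' Remodelling parameters
#'
#' The calibrated quantities of the mechanoregulation update
#' `dTMD = B * (Theta - k)` applied per time step, with an optional lazy zone
#' of half-width `w` about the apposition limit inside which no response
#' occurs, and the TMD clamp applied to every output image.
#'
#' @slot B remodelling rate, mg/cc per stimulus unit per time step.
#' @slot k apposition limit (stimulus threshold), Pa (SED) or microstrain.
#' @slot w lazy-zone half-width, same units as `k` (0 = no lazy zone).
#' @slot tmdMin,tmdMax TMD clamp, mg/cc.
#' @slot timeStepWeeks duration represented by one update.
#' @export
setClass("RemodellingParams",
  representation(B = "numeric", k = "numeric", w = "numeric",
                 tmdMin = "numeric", tmdMax = "numeric",
                 timeStepWeeks = "numeric"),
  prototype(w = 0, tmdMin = 0, tmdMax = 1400, timeStepWeeks = 2))

setValidity("RemodellingParams", function(object) {
  if (object@B < 0) return("B must be >= 0")
  if (object@k < 0) return("k must be >= 0")
  if (object@w < 0) return("w must be >= 0")
  if (object@tmdMin >= object@tmdMax) return("tmdMin must be < tmdMax")
  TRUE
})

#' @param B,k,w,tmdMin,tmdMax,timeStepWeeks see slot documentation.
#' @rdname RemodellingParams-class
#' @export
remodellingParams <- function(B, k, w = 0, tmdMin = 0, tmdMax = 1400,
                              timeStepWeeks = 2) {
  new("RemodellingParams", B = B, k = k, w = w, tmdMin = tmdMin,
      tmdMax = tmdMax, timeStepWeeks = timeStepWeeks)
}

#' Compartment atlas
#'
#' Per-voxel longitudinal section index (1 = distal to `nSections` =
#' proximal; 0 outside the occupied extent) and angular sector label
#' (anterior / posterior / medial / lateral quadrants about the whole-bone
#' centroid axis, boundaries at the 45-degree diagonals).
#'
#' @slot section integer 3D array of section indices.
#' @slot sector integer 3D array: 1 anterior, 2 posterior, 3 medial,
#'   4 lateral.
#' @slot nSections number of longitudinal sections.
#' @slot spacing voxel edge length, micrometres.
#' @export
setClass("CompartmentAtlas",
  representation(section = "array", sector = "array", nSections = "integer",
                 spacing = "numeric"))

#' Sectional volumetric second moments
#'
#' Per-section volumetric second moments of the bone about the section's own
#' bone centroid, in mm^5: `Ixx = sum (y - ybar)^2 dV`,
#' `Iyy = sum (x - xbar)^2 dV`.
#'
#' @slot section section index, distal to proximal.
#' @slot Ixx,Iyy volumetric second moments, mm^5.
#' @export
setClass("SecondMomentProfile",
  representation(section = "integer", Ixx = "numeric", Iyy = "numeric"))

setValidity("SecondMomentProfile", function(object) {
  if (any(object@Ixx < 0) || any(object@Iyy < 0))
    return("second moments must be non-negative")
  TRUE
})

#' Densitometric report
#'
#' Bone volume (BV, mm^3), total volume enclosed by the periosteal surface
#' (TV, mm^3), BV/TV, bone mineral content (BMC, mg), volumetric bone mineral
#' density (BMD, mg/cc) and mean TMD (mg/cc), for the whole bone and each
#' compartment of the atlas.
#'
#' @slot table data.frame with columns region, section, sector, BV, TV,
#'   BVTV, BMC, BMD, meanTMD.
#' @export
setClass("DensitometricReport", representation(table = "data.frame"))

#' Remodelling site map
#'
#' Voxels of the earlier-time surface shell whose bone/background state
#' changes between two aligned images: apposition (background to bone) and
#' resorption (bone to background), each labelled endosteal or periosteal.
#'
#' @slot sites data.frame with columns index (linear voxel index), direction
#'   (`"apposition"`/`"resorption"`), surface (`"endosteal"`/`"periosteal"`).
#' @slot dims image dimensions the indices refer to.
#' @slot provenance free-text description of the image pair.
#' @export
setClass("RemodellingSiteMap",
  representation(sites = "data.frame", dims = "integer",
                 provenance = "character"))

setValidity("RemodellingSiteMap", function(object) {
  s <- object@sites
  app <- s$index[s$direction == "apposition"]
  res <- s$index[s$direction == "resorption"]
  if (length(intersect(app, res)) > 0)
    return("apposition and resorption sites must be disjoint")
  TRUE
})

#' Calibration problem
#'
#' A longitudinal image pair plus everything needed to run the forward model
#' and the grid-multistart constrained fit of the remodelling rate and
#' apposition limit (optionally also the lazy-zone half-width).
#'
#' @slot baseline,followUp aligned grey-value [VoxelImage-class]s.
#' @slot seg [SegmentationModel-class] from the baseline scan.
#' @slot cal [DensitometricCalibration-class].
#' @slot bodyMass grams.
#' @slot stimulusKind `"sed"` or `"maxprinc"`.
#' @slot nSections sections for the second-moment objective.
#' @slot optimiseLazyZone fit the lazy-zone half-width as a third parameter.
#' @slot gridB,gridK multistart grid ranges for B and k.
#' @slot gridN grid dimensions, e.g. `c(10, 10)` for 100 starts.
#' @slot seed seed for any randomised start jitter.
#' @export
setClass("CalibrationProblem",
  representation(baseline = "VoxelImage", followUp = "VoxelImage",
                 seg = "SegmentationModel", cal = "DensitometricCalibration",
                 bodyMass = "numeric", stimulusKind = "character",
                 nSections = "integer", optimiseLazyZone = "logical",
                 gridB = "numeric", gridK = "numeric", gridN = "integer",
                 seed = "integer"))

setValidity("CalibrationProblem", function(object) {
  if (!identical(dim(object@baseline@data), dim(object@followUp@data)))
    return("baseline and follow-up must be aligned (equal dimensions)")
  if (prod(object@gridN) < 1) return("grid must contain at least one start")
  if (object@bodyMass <= 0) return("body mass must be positive")
  TRUE
})

#' Calibration result
#'
#' @slot B,k,w fitted parameters (w = 0 when the lazy zone is not fitted).
#' @slot value objective at the optimum (sum of squared mm^5 residuals).
#' @slot trace per-start data.frame of starts, optima and convergence codes.
#' @slot converged best start's local convergence flag.
#' @slot nonIdentifiable `TRUE` when a zero-remodelling model fits as well as
#'   the optimum (no signal between the two time points).
#' @export
setClass("CalibrationResult",
  representation(B = "numeric", k = "numeric", w = "numeric",
                 value = "numeric", trace = "data.frame",
                 converged = "logical", nonIdentifiable = "logical"))

setValidity("CalibrationResult", function(object) {
  if (object@B <= 0 || object@k <= 0) return("B and k must be positive")
  if (object@value < 0) return("objective must be non-negative")
  TRUE
})

#' Phantom specification
#'
#' Geometry and grey-value statistics of a synthetic, pre-aligned cortical
#' bone tube: a tapered hollow cylinder along z with Gaussian-jittered
#' bone/background values, Gaussian surface blur emulating the partial
#' volume effect, and a fixed noise seed. All generators are pure functions
#' of the spec.
#'
#' @slot dims grid dimensions (nx, ny, nz).
#' @slot spacing voxel edge length, micrometres.
#' @slot outerRadius outer radius at the distal and proximal ends, voxels.
#' @slot wallThickness wall thickness at the distal and proximal ends,
#'   voxels (>= 1).
#' @slot lumenOffset in-plane offset of the lumen centre, voxels.
#' @slot boneTmd mean and SD of bone TMD, mg/cc.
#' @slot backgroundTmd mean and SD of background TMD, mg/cc.
#' @slot blurSigma partial-volume blur SD, voxels.
#' @slot seed noise seed.
#' @export
setClass("PhantomSpec",
  representation(dims = "integer", spacing = "numeric",
                 outerRadius = "numeric", wallThickness = "numeric",
                 lumenOffset = "numeric", boneTmd = "numeric",
                 backgroundTmd = "numeric", blurSigma = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(object@wallThickness < 1))
    return("wall thickness must be >= 1 voxel")
  rmax <- max(object@outerRadius) + max(abs(object@lumenOffset))
  if (2 * rmax > min(object@dims[1:2]))
    return("tube geometry exceeds the grid")
  if (any(object@outerRadius - object@wallThickness < 0))
    return("wall thicker than the outer radius")
  TRUE
})

#' @param dims,spacing,outerRadius,wallThickness,lumenOffset,boneTmd,backgroundTmd,blurSigma,seed
#'   see slot documentation.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(dims = c(40L, 40L, 120L), spacing = 40,
                        outerRadius = c(12, 10), wallThickness = c(4, 4),
                        lumenOffset = c(0, 0), boneTmd = c(900, 30),
                        backgroundTmd = c(100, 20), blurSigma = 0.7,
                        seed = 42L) {
  new("PhantomSpec", dims = as.integer(dims), spacing = spacing,
      outerRadius = outerRadius, wallThickness = wallThickness,
      lumenOffset = lumenOffset, boneTmd = boneTmd,
      backgroundTmd = backgroundTmd, blurSigma = blurSigma,
      seed = as.integer(seed))
}
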