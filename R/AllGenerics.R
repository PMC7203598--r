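#' @include AllClasses.R
NULL

#' Voxel data of an image or mask
#' @param x a [VoxelImage-class] or [BoneMask-class].
#' @return the underlying 3D array.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname imgData
#' @export
setMethod("imgData", "VoxelImage", function(x) x@data)

#' @rdname imgData
#' @export
setMethod("imgData", "BoneMask", function(x) x@mask)

#' Voxel spacing in micrometres
#' @param x an object carrying a voxel grid.
#' @return isotropic voxel edge length, micrometres.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "VoxelImage", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "BoneMask", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "CompartmentAtlas", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "StimulusField", function(x) x@spacing)

#' Value unit of a VoxelImage
#' @param x a [VoxelImage-class].
#' @return `"grey"` or `"mg/cc"`.
#' @export
setGeneric("imgUnit", function(x) standardGeneric("imgUnit"))

#' @rdname imgUnit
#' @export
setMethod("imgUnit", "VoxelImage", function(x) x@unit)

#' @export
setMethod("dim", "VoxelImage", function(x) dim(x@data))

#' @export
setMethod("dim", "BoneMask", function(x) dim(x@mask))

#' Extract the result table of a report object
#' @param x a report object.
#' @return a data.frame.
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname reportTable
#' @export
setMethod("reportTable", "DensitometricReport", function(x) x@table)

#' @rdname reportTable
#' @export
setMethod("reportTable", "RemodellingSiteMap", function(x) x@sites)

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelImage %d x %d x %d, spacing %.4g um, unit %s\n",
              d[1], d[2], d[3], object@spacing, object@unit))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(object@data),
              max(object@data)))
})

setMethod("show", "BoneMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BoneMask %d x %d x %d, spacing %.4g um, %d bone voxels\n",
              d[1], d[2], d[3], object@spacing, sum(object@mask)))
})

setMethod("show", "SegmentationModel", function(object) {
  cat(sprintf("SegmentationModel: threshold %.4g, transition zone [%.4g, %.4g]\n",
              object@threshold, object@tzLow, object@tzHigh))
})

setMethod("show", "FEModel", function(object) {
  cat(sprintf(paste0("FEModel: %d hexahedral elements, %d nodes ",
                     "(%d fixed, %d coupled)\n"),
              nrow(object@elems), nrow(object@nodeIJK),
              sum(object@nodeType == 1L), sum(object@nodeType == 2L)))
  cat(sprintf("  E = %.4g Pa, nu = %.3g, voxel %.4g um\n", object@E,
              object@nu, object@spacing))
})

setMethod("show", "StimulusField", function(object) {
  un <- if (object@kind == "sed") "Pa" else "ustrain"
  cat(sprintf("StimulusField (%s): %d surface nodes, range [%.4g, %.4g] %s\n",
              object@kind, length(object@values), min(object@values),
              max(object@values), un))
})

setMethod("show", "RemodellingParams", function(object) {
  cat(sprintf(paste0("RemodellingParams: B = %.4g mg/cc per stimulus unit, ",
                     "k = %.4g, lazy half-width %.4g\n"),
              object@B, object@k, object@w))
  cat(sprintf("  TMD clamp [%g, %g] mg/cc, time step %g weeks\n",
              object@tmdMin, object@tmdMax, object@timeStepWeeks))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: B = %.4g, k = %.4g, w = %.4g\n",
              object@B, object@k, object@w))
  cat(sprintf("  objective %.6g over %d starts; converged: %s%s\n",
              object@value, nrow(object@trace), object@converged,
              if (object@nonIdentifiable) " (non-identifiable)" else ""))
})

setMethod("show", "DensitometricReport", function(object) {
  cat("DensitometricReport\n")
  print(head(object@table, 5))
  if (nrow(object@table) > 5)
    cat(sprintf("  ... %d regions in total\n", nrow(object@table)))
})

setMethod("show", "RemodellingSiteMap", function(object) {
  s <- object@sites
  cat(sprintf("RemodellingSiteMap (%s): %d apposition, %d resorption sites\n",
              object@provenance, sum(s$direction == "apposition"),
              sum(s$direction == "resorption")))
})

#' @export
setMethod("as.data.frame", "SecondMomentProfile", function(x, ...) {
  data.frame(section = x@section, Ixx = x@Ixx, Iyy = x@Iyy)
})
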