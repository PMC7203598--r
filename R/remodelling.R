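#' @include microfe.R
NULL

#' Mechanoregulation response: change in TMD per time step
#'
#' `dTMD = B * (Theta - k)` for stimulus excess outside the lazy zone;
#' stimuli within `k +/- w` (band edges inclusive) elicit no response.
#' `w = 0` reproduces the base model without a lazy zone.
#'
#' @param theta mechanical stimulus (Pa for SED, microstrain for the maximum
#'   principal strain); vectorised.
#' @param params a [RemodellingParams-class].
#' @return change in TMD, mg/cc per time step.
#' @export
deltaTmd <- function(theta, params) {
  stopifnot(all(is.finite(theta)))
  ifelse(abs(theta - params@k) <= params@w, 0,
         params@B * (theta - params@k))
}

#' Convert an SED value to an equivalent uniaxial microstrain
#'
#' Under the uniaxial equivalence `SED = E * eps^2 / 2`, an SED stimulus
#' corresponds to `eps = sqrt(2 * SED / E)`, reported in microstrain. Useful
#' for comparing SED apposition limits with strain-gauge literature.
#'
#' @param sed strain energy density, Pa (>= 0).
#' @param E elastic modulus, Pa.
#' @return equivalent strain in microstrain.
#' @export
sedToMicrostrain <- function(sed, E = 14.8e9) {
  if (any(sed < 0)) stop("SED must be non-negative")
  if (E <= 0) stop("E must be positive")
  sqrt(2 * sed / E) * 1e6
}

#' Clamp a TMD image to the physical range
#'
#' @param image a [VoxelImage-class] in mg/cc.
#' @param params a [RemodellingParams-class] carrying `tmdMin`, `tmdMax`
#'   (defaults 0 and 1400 mg/cc).
#' @return the clamped [VoxelImage-class].
#' @export
applyClamp <- function(image, params) {
  VoxelImage(pmin(pmax(image@data, params@tmdMin), params@tmdMax),
             image@spacing, image@unit)
}

# per-voxel role labels for the BRU update: 0 background (below the
# transition zone), 1 transition zone, 2 bone (above it); bounds in the same
# units as the image values
.voxelRoles <- function(values, tzLow, tzHigh) {
  r <- integer(length(values))
  r[values >= tzLow & values <= tzHigh] <- 1L
  r[values > tzHigh] <- 2L
  r
}

#' BRU-lattice density update
#'
#' Applies the node-centred bone remodelling unit update to a TMD image.
#' Each surface node drives the mean TMD of its 8 incident voxels towards
#' `mean + dTMD` by one multiplicative factor applied to the
#' direction-dependent voxel set: apposition scales the background and
#' transition-zone voxels, resorption scales the bone and transition-zone
#' voxels (TZ voxels remodel in both directions). Each voxel's new TMD is
#' the average over the targets proposed by all its contributing surface
#' nodes; voxels with no contributing node are unchanged. The result is
#' clamped to `[tmdMin, tmdMax]`.
#'
#' Pure-zero background makes multiplicative apposition ill-posed, so values
#' in the scaled set are floored at `backgroundFloor` (mg/cc) before
#' scaling. A BRU whose scaled set is empty (or whose factor would be
#' negative) proposes the unchanged values; such saturated BRUs are counted
#' in the `saturated` attribute of the result.
#'
#' @param image a [VoxelImage-class] in mg/cc.
#' @param seg a [SegmentationModel-class] in grey units.
#' @param stimulus a [StimulusField-class] defined on the surface nodes of
#'   the current bone mask.
#' @param params a [RemodellingParams-class].
#' @param cal the [DensitometricCalibration-class] used to express the
#'   segmentation bounds in mg/cc (identity by default, for images whose
#'   grey values already are TMD).
#' @param backgroundFloor minimum TMD used inside the scaled set, mg/cc.
#' @return the updated [VoxelImage-class] (mg/cc), with attribute
#'   `saturated`.
#' @export
bruUpdate <- function(image, seg, stimulus, params,
                      cal = densitometricCalibration(), backgroundFloor = 1) {
  if (image@unit != "mg/cc") stop("bruUpdate expects a TMD image (mg/cc)")
  thrT <- cal@slope * seg@threshold + cal@intercept
  tzLowT <- cal@slope * seg@tzLow + cal@intercept
  tzHighT <- cal@slope * seg@tzHigh + cal@intercept
  d <- dim(image@data)
  if (!identical(as.integer(d), as.integer(stimulus@dims)))
    stop("stimulus field and image dimensions disagree")
  # the stimulus must sit on surface nodes of the current mask
  m <- image@data > thrT
  sg <- .surface_node_grid(as.vector(m), d)
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  gid <- stimulus@nodeIJK[, 1] + nx1 * (stimulus@nodeIJK[, 2] +
                                        ny1 * stimulus@nodeIJK[, 3])
  if (!all(sg[gid + 1L]))
    stop("stimulus node set does not lie on the surface of the current mask")
  roles <- .voxelRoles(as.vector(image@data), tzLowT, tzHighT)
  delta <- deltaTmd(stimulus@values, params)
  res <- .bru_update(as.vector(image@data), d, roles, stimulus@nodeIJK,
                     delta, backgroundFloor)
  newVals <- as.vector(image@data)
  touched <- res$propcount > 0L
  newVals[touched] <- newVals[touched] +
    res$dsum[touched] / res$propcount[touched]
  out <- applyClamp(VoxelImage(array(newVals, d), image@spacing, "mg/cc"),
                    params)
  attr(out@data, "saturated") <- NULL
  structure(out, saturated = res$saturated)
}

#' Simulate one remodelling time step
#'
#' Orchestrates a full 2-week iteration on a grey-value image: binarise at
#' the subject's threshold, keep the largest face-connected component, build
#' and solve the micro-FE model under unit loads, superpose the
#' physiological load for the given body mass, compute the nodal stimulus,
#' apply the BRU update in TMD space, clamp, and convert back to grey
#' values. Voxels whose TMD is unchanged keep their grey value bit-exactly.
#' Deterministic: repeated runs yield identical output.
#'
#' @param image a [VoxelImage-class] in grey units.
#' @param seg a [SegmentationModel-class] (from the baseline scan).
#' @param cal a [DensitometricCalibration-class].
#' @param bodyMass grams.
#' @param params a [RemodellingParams-class].
#' @param kind stimulus kind, `"sed"` or `"maxprinc"`.
#' @param E,nu material constants, Pa / unitless.
#' @param tol,maxit FE solver controls.
#' @param stimulus optional precomputed [StimulusField-class] for this
#'   image (skips the FE solve; used by the calibration loop, where the
#'   baseline mask — and hence the elastic solution — is fixed).
#' @return the predicted grey-value [VoxelImage-class] one time step later.
#' @export
simulateStep <- function(image, seg, cal, bodyMass, params,
                         kind = c("sed", "maxprinc"), E = 14.8e9, nu = 0.3,
                         tol = 1e-8, maxit = 1e5, stimulus = NULL) {
  kind <- match.arg(kind)
  if (is.null(stimulus))
    stimulus <- .stimulusForImage(image, seg, bodyMass, kind, E, nu, tol,
                                  maxit)
  tmd <- greyToTmd(image, cal)
  updated <- bruUpdate(tmd, seg, stimulus, params, cal)
  grey <- tmdToGrey(updated, cal)
  unchanged <- updated@data == tmd@data
  grey@data[unchanged] <- image@data[unchanged]
  structure(grey, saturated = attr(updated, "saturated"))
}

#' Construct a stimulus field directly on a mask's surface nodes
#'
#' Builds a [StimulusField-class] with prescribed values (recycled scalar or
#' one value per surface node, in scan order of the node lattice) on the
#' surface nodes of a mask, bypassing the FE solve. Useful for exploring the
#' BRU update in isolation.
#'
#' @param mask a [BoneMask-class].
#' @param values scalar or per-surface-node stimulus values.
#' @param kind `"sed"` or `"maxprinc"`.
#' @return A [StimulusField-class].
#' @export
surfaceStimulusField <- function(mask, values, kind = c("sed", "maxprinc")) {
  kind <- match.arg(kind)
  d <- dim(mask@mask)
  sg <- array(.surface_node_grid(as.vector(mask@mask), d),
              d + 1L)
  ijk <- which(sg, arr.ind = TRUE) - 1L
  storage.mode(ijk) <- "integer"
  vals <- rep_len(values, nrow(ijk))
  new("StimulusField", kind = kind, values = as.numeric(vals),
      nodeIJK = ijk, dims = as.integer(d), spacing = mask@spacing)
}

# binarise -> largest component -> FE unit loads -> superposed physiological
# load -> nodal stimulus, for one grey image
.stimulusForImage <- function(image, seg, bodyMass, kind, E = 14.8e9,
                              nu = 0.3, tol = 1e-8, maxit = 1e5) {
  mask <- largestComponent(binarise(image, seg@threshold))
  model <- buildFEModel(mask, E = E, nu = nu)
  load <- physiologicalLoad(bodyMass)
  dirs <- names(load)[abs(load) > 0]
  fields <- solveUnitLoads(model, directions = dirs, tol = tol,
                           maxit = maxit)
  u <- superpose(fields, load)
  computeStimulusField(model, u, kind)
}
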