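#' @include voxel-image.R
NULL

# local hexahedral corner ordering; must match the element stiffness matrix:
# 0:(0,0,0) 1:(1,0,0) 2:(1,1,0) 3:(0,1,0) 4:(0,0,1) 5:(1,0,1) 6:(1,1,1)
# 7:(0,1,1) in voxel-corner offsets
.hexOffsets <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                        0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
                      ncol = 3, byrow = TRUE)

#' Build a voxel micro-finite-element model from a bone mask
#'
#' Converts every bone voxel into a linear 8-node hexahedral element with
#' homogeneous isotropic material. All elements are identical cubes, so a
#' single element stiffness matrix is shared. Boundary conditions follow the
#' longitudinal axis convention: the proximal (max z) node layer is fully
#' constrained and the distal (min z) node layer is kinematically coupled to
#' a rotation-fixed reference point at the distal area centroid. Internally
#' SI units are used (m, N, Pa).
#'
#' @param mask a single face-connected [BoneMask-class] (see
#'   [largestComponent()]).
#' @param E elastic modulus, Pa (default 14.8 GPa, cortical mouse bone).
#' @param nu Poisson ratio (default 0.3).
#' @return An [FEModel-class].
#' @export
buildFEModel <- function(mask, E = 14.8e9, nu = 0.3) {
  m <- mask@mask
  if (!any(m)) stop("empty mask")
  if (countComponents(mask, "face") > 1L)
    stop("mask has multiple face-connected components; ",
         "apply largestComponent() first")
  d <- dim(m)
  vox <- which(m, arr.ind = TRUE) - 1L # 0-based
  ne <- nrow(vox)
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  gids <- matrix(0L, ne, 8)
  for (a in 1:8) {
    o <- .hexOffsets[a, ]
    gids[, a] <- (vox[, 1] + o[1]) + nx1 * ((vox[, 2] + o[2]) +
                                            ny1 * (vox[, 3] + o[3]))
  }
  uniq <- sort(unique(as.vector(gids)))
  elems <- matrix(match(gids, uniq) - 1L, ne, 8)
  kk <- uniq %/% (nx1 * ny1)
  rr <- uniq %% (nx1 * ny1)
  nodeIJK <- cbind(rr %% nx1, rr %/% nx1, kk)
  storage.mode(nodeIJK) <- "integer"
  h <- mask@spacing * 1e-6
  model <- new("FEModel", elems = elems, nodeIJK = nodeIJK,
               nodeType = integer(nrow(nodeIJK)), voxIJK = vox,
               dims = as.integer(d), spacing = mask@spacing, E = E, nu = nu,
               ke = .hex_ke(h, E, nu), refPoint = numeric(3))
  applyBoundaryConditions(model)
}

#' Apply the proximal/distal boundary conditions
#'
#' Marks the proximal (max z) node layer fully constrained and the distal
#' (min z) layer coupled, and places the distal reference point at the area
#' centroid of the distal surface. Called automatically by [buildFEModel()];
#' exported so alternative constraint layouts can be rebuilt after editing.
#'
#' @param model an [FEModel-class].
#' @return the model with constraint sets populated.
#' @export
applyBoundaryConditions <- function(model) {
  kz <- model@nodeIJK[, 3]
  kmax <- max(kz); kmin <- min(kz)
  if (kmax == kmin)
    stop("model is a single node layer; proximal and distal sets coincide")
  nodeType <- integer(length(kz))
  nodeType[kz == kmax] <- 1L # proximal, fixed
  nodeType[kz == kmin] <- 2L # distal, coupled
  if (!any(nodeType == 1L) || !any(nodeType == 2L))
    stop("empty constraint set")
  h <- model@spacing * 1e-6
  model@nodeType <- nodeType
  model@refPoint <- colMeans(model@nodeIJK[nodeType == 2L, , drop = FALSE]) * h
  validObject(model)
  model
}

#' Physiological load vector from body mass
#'
#' Peak walking loads at the ankle joint scale linearly with body mass:
#' 0.01355 N/g along superior--inferior, 0.00289 N/g along
#' anterior--posterior and zero along medial--lateral.
#'
#' @param bodyMass grams.
#' @return named numeric `c(ml, ap, si)` in Newtons.
#' @export
physiologicalLoad <- function(bodyMass) {
  if (!is.finite(bodyMass) || bodyMass <= 0)
    stop("body mass must be positive")
  c(ml = 0, ap = 0.00289 * bodyMass, si = 0.01355 * bodyMass)
}

.solveOne <- function(model, f, tol, maxit) {
  res <- .fe_solve(model@elems, model@nodeType, model@ke, f, tol,
                   as.integer(maxit))
  if (!res$converged)
    stop(sprintf("FE solver did not converge: relative residual %.3g after %d iterations",
                 res$relres, res$iters))
  new("DisplacementField", values = res$u, load = c(ml = f[1], ap = f[2],
                                                    si = f[3]),
      iters = as.integer(res$iters), relres = res$relres)
}

#' Solve the unit-load cases
#'
#' Solves `K u = f` for a 1 N load applied at the distal reference point
#' along each requested anatomical axis, using a matrix-free Jacobi-
#' preconditioned conjugate gradient method. The three fields are combined
#' for arbitrary loads with [superpose()] (the model is linear).
#'
#' @param model an [FEModel-class].
#' @param directions subset of `c("ml", "ap", "si")`.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return named list of [DisplacementField-class]s.
#' @export
solveUnitLoads <- function(model, directions = c("ml", "ap", "si"),
                           tol = 1e-8, maxit = 1e5) {
  directions <- match.arg(directions, c("ml", "ap", "si"),
                          several.ok = TRUE)
  axes <- list(ml = c(1, 0, 0), ap = c(0, 1, 0), si = c(0, 0, 1))
  out <- lapply(directions, function(d)
    .solveOne(model, axes[[d]], tol, maxit))
  names(out) <- directions
  out
}

#' Solve a single load case directly
#'
#' @param model an [FEModel-class].
#' @param load named numeric `c(ml, ap, si)` in Newtons.
#' @inheritParams solveUnitLoads
#' @return A [DisplacementField-class].
#' @export
solveLoad <- function(model, load, tol = 1e-8, maxit = 1e5) {
  .solveOne(model, as.numeric(load[c("ml", "ap", "si")]), tol, maxit)
}

#' Superpose unit-load displacement fields
#'
#' Weighted sum of unit-load fields by the load components. Superposition is
#' applied to displacements (and hence strains), never to SED values, which
#' are quadratic in strain; compute the stimulus after superposing.
#'
#' @param unitFields named list of [DisplacementField-class]s from
#'   [solveUnitLoads()]; entries may be omitted for zero load components.
#' @param load named numeric `c(ml, ap, si)` in Newtons.
#' @return A [DisplacementField-class].
#' @export
superpose <- function(unitFields, load) {
  load <- load[c("ml", "ap", "si")]
  need <- names(load)[abs(load) > 0]
  miss <- setdiff(need, names(unitFields))
  if (length(miss) > 0)
    stop("missing unit field(s) for nonzero load component(s): ",
         paste(miss, collapse = ", "))
  nn <- vapply(unitFields, function(f) nrow(f@values), 1L)
  if (length(unique(nn)) > 1) stop("unit fields come from different models")
  u <- matrix(0, nn[1], 3)
  for (d in need) u <- u + load[[d]] * unitFields[[d]]@values
  new("DisplacementField", values = u, load = load,
      iters = max(vapply(unitFields[need], slot, 1L, "iters"), 0L),
      relres = max(vapply(unitFields[need], slot, 1, "relres"), 0))
}

#' Surface nodes of a model
#'
#' Nodes incident to at least one element face not shared with another
#' element. Only these carry the remodelling stimulus.
#'
#' @param model an [FEModel-class].
#' @return integer indices into the model's node set.
#' @export
surfaceNodes <- function(model) {
  m <- array(FALSE, model@dims)
  m[model@voxIJK + 1L] <- TRUE
  sg <- .surface_node_grid(as.vector(m), model@dims)
  nx1 <- model@dims[1] + 1L; ny1 <- model@dims[2] + 1L
  gid <- model@nodeIJK[, 1] + nx1 * (model@nodeIJK[, 2] +
                                     ny1 * model@nodeIJK[, 3])
  which(sg[gid + 1L])
}

#' Compute the nodal mechanical stimulus field
#'
#' Strains at the 2x2x2 Gauss points of each element are extrapolated to the
#' element corners by the standard trilinear rule and averaged over all
#' elements sharing a node. For SED the scalar `0.5 * sigma : eps` is
#' extrapolated; for the maximum principal strain the six strain components
#' are extrapolated and averaged first and the largest eigenvalue of the
#' nodal tensor taken last. Output is restricted to surface nodes.
#'
#' @param model an [FEModel-class].
#' @param u a [DisplacementField-class] solving the model.
#' @param kind `"sed"` (Pa) or `"maxprinc"` (microstrain).
#' @return A [StimulusField-class].
#' @export
computeStimulusField <- function(model, u, kind = c("sed", "maxprinc")) {
  kind <- match.arg(kind)
  if (nrow(u@values) != nrow(model@nodeIJK))
    stop("displacement field does not match the model")
  h <- model@spacing * 1e-6
  res <- .stimulus_nodal(model@elems, u@values, nrow(model@nodeIJK), h,
                         model@E, model@nu, if (kind == "sed") 0L else 1L)
  surf <- surfaceNodes(model)
  vals <- res$value[surf]
  if (kind == "sed") vals <- pmax(vals, 0) else vals <- vals * 1e6
  new("StimulusField", kind = kind, values = vals,
      nodeIJK = model@nodeIJK[surf, , drop = FALSE], dims = model@dims,
      spacing = model@spacing)
}

#' Total strain energy of a solved load case
#'
#' `0.5 * f' u`, evaluated at the distal reference point (the only loaded
#' DOF set). Positive for any nonzero load.
#'
#' @param model an [FEModel-class].
#' @param u a [DisplacementField-class].
#' @return energy in Joules.
#' @export
strainEnergy <- function(model, u) {
  distal <- model@nodeType == 2L
  uref <- colMeans(u@values[distal, , drop = FALSE])
  0.5 * sum(as.numeric(u@load) * uref)
}
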