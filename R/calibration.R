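#' @include metrics.R
NULL

#' Define a calibration problem
#'
#' @param baseline,followUp aligned grey-value [VoxelImage-class]s one time
#'   step apart.
#' @param seg a [SegmentationModel-class] (from the baseline scan).
#' @param cal a [DensitometricCalibration-class].
#' @param bodyMass grams.
#' @param stimulusKind `"sed"` or `"maxprinc"`.
#' @param nSections sections for the second-moment objective (default 10).
#' @param optimiseLazyZone also fit the lazy-zone half-width.
#' @param gridB,gridK multistart grid ranges (default 0.01--1 mg/cc-Pa and
#'   0.1--50 Pa, bracketing physiological SED calibrations).
#' @param gridN grid dimensions; `c(10, 10)` gives 100 starts.
#' @param seed seed for any randomised start jitter.
#' @return A [CalibrationProblem-class].
#' @export
calibrationProblem <- function(baseline, followUp, seg, cal, bodyMass,
                               stimulusKind = c("sed", "maxprinc"),
                               nSections = 10, optimiseLazyZone = FALSE,
                               gridB = c(0.01, 1), gridK = c(0.1, 50),
                               gridN = c(10, 10), seed = 1L) {
  stimulusKind <- match.arg(stimulusKind)
  new("CalibrationProblem", baseline = baseline, followUp = followUp,
      seg = seg, cal = cal, bodyMass = bodyMass,
      stimulusKind = stimulusKind, nSections = as.integer(nSections),
      optimiseLazyZone = optimiseLazyZone, gridB = gridB, gridK = gridK,
      gridN = as.integer(gridN), seed = as.integer(seed))
}

# everything about the problem that does not depend on (B, k): the baseline
# stimulus field and TMD image, and the follow-up's second-moment profile.
# Within a one-step calibration the baseline mask is fixed, so the elastic
# solution is computed once and reused exactly.
.calibrationCache <- function(problem) {
  stim <- .stimulusForImage(problem@baseline, problem@seg, problem@bodyMass,
                            problem@stimulusKind)
  tmd <- greyToTmd(problem@baseline, problem@cal)
  thrT <- problem@cal@slope * problem@seg@threshold + problem@cal@intercept
  fuMask <- binarise(problem@followUp, problem@seg@threshold)
  fuProf <- volumetricSecondMoments(
    fuMask, buildAtlas(fuMask, problem@nSections))
  list(stimulus = stim, tmd = tmd, thrT = thrT, fuProf = fuProf)
}

.profileOfTmd <- function(tmdImage, thrT, nSections) {
  mask <- BoneMask(tmdImage@data > thrT, tmdImage@spacing)
  volumetricSecondMoments(mask, buildAtlas(mask, nSections))
}

#' Calibration objective: sectional second-moment residual
#'
#' Runs one remodelling step on the baseline with the candidate parameters
#' and returns the sum of squared per-section residuals (mm^10) between the
#' predicted and follow-up volumetric second moments:
#' `sum (Ixx_exp - Ixx_pred)^2 + sum (Iyy_exp - Iyy_pred)^2`. A failed
#' simulation yields `+Inf` with a warning so multistart optimisation stays
#' robust.
#'
#' @param params a [RemodellingParams-class].
#' @param problem a [CalibrationProblem-class].
#' @param cache precomputed invariants from the baseline image (internal;
#'   built on the fly when `NULL`).
#' @param squared use squared residuals (`TRUE`, the least-squares reading);
#'   `FALSE` sums plain residuals, for sensitivity checks.
#' @return the residual (non-negative for `squared = TRUE`).
#' @export
calibrationObjective <- function(params, problem, cache = NULL,
                                 squared = TRUE) {
  if (is.null(cache)) cache <- .calibrationCache(problem)
  val <- tryCatch({
    pred <- bruUpdate(cache$tmd, problem@seg, cache$stimulus, params,
                      problem@cal)
    prof <- .profileOfTmd(pred, cache$thrT, problem@nSections)
    dx <- cache$fuProf@Ixx - prof@Ixx
    dy <- cache$fuProf@Iyy - prof@Iyy
    if (squared) sum(dx^2) + sum(dy^2) else sum(dx) + sum(dy)
  }, error = function(e) {
    warning("objective evaluation failed: ", conditionMessage(e))
    Inf
  })
  val
}

#' Calibrate remodelling parameters from a longitudinal pair
#'
#' Grid multistart over `(B, k)` (log-spaced lattice across the stated
#' ranges, optionally jittered) followed by a Nelder--Mead local
#' minimisation in log-parameter space, which enforces the positivity
#' constraints `B > 0`, `k > 0` (and `w >= 0` when the lazy zone is fitted)
#' exactly. The best local optimum over all starts is returned.
#' Deterministic for a fixed grid and seed.
#'
#' @param problem a [CalibrationProblem-class].
#' @param maxit Nelder--Mead iteration cap per start.
#' @param reltol Nelder--Mead relative convergence tolerance.
#' @param jitter multiplicative log-uniform jitter half-width applied to the
#'   grid starts (0 = plain lattice).
#' @return A [CalibrationResult-class].
#' @export
calibrate <- function(problem, maxit = 200, reltol = 1e-8, jitter = 0) {
  cache <- .calibrationCache(problem)
  nB <- problem@gridN[1]; nK <- problem@gridN[2]
  gB <- exp(seq(log(problem@gridB[1]), log(problem@gridB[2]),
                length.out = nB))
  gK <- exp(seq(log(problem@gridK[1]), log(problem@gridK[2]),
                length.out = nK))
  starts <- expand.grid(B = gB, k = gK)
  if (jitter > 0) {
    starts <- withSeed(problem@seed, {
      n <- nrow(starts)
      data.frame(B = starts$B * exp(runif(n, -jitter, jitter)),
                 k = starts$k * exp(runif(n, -jitter, jitter)))
    })
  }
  lz <- problem@optimiseLazyZone
  mkParams <- function(x) {
    remodellingParams(B = x[1], k = x[2], w = if (lz) x[3] else 0)
  }
  fn <- function(lp) {
    calibrationObjective(mkParams(exp(lp)), problem, cache)
  }
  trace <- data.frame()
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- log(c(starts$B[i], starts$k[i],
                  if (lz) 0.05 * starts$k[i] else NULL))
    fit <- tryCatch(
      optim(par0, fn, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) {
      trace <- rbind(trace, data.frame(
        startB = starts$B[i], startK = starts$k[i], B = NA, k = NA, w = NA,
        value = Inf, convergence = NA_integer_))
      next
    }
    p <- exp(fit$par)
    trace <- rbind(trace, data.frame(
      startB = starts$B[i], startK = starts$k[i], B = p[1], k = p[2],
      w = if (lz) p[3] else 0, value = fit$value,
      convergence = fit$convergence))
    if (is.null(best) || fit$value < best$value)
      best <- list(par = p, value = fit$value,
                   converged = fit$convergence == 0L)
  }
  if (is.null(best) || !is.finite(best$value))
    stop("calibration failed for every start; see the trace")
  # a pair with no signal fits a zero-remodelling model as well as the best
  objZero <- {
    prof0 <- .profileOfTmd(cache$tmd, cache$thrT, problem@nSections)
    sum((cache$fuProf@Ixx - prof0@Ixx)^2) +
      sum((cache$fuProf@Iyy - prof0@Iyy)^2)
  }
  nonId <- objZero <= best$value + 1e-12 * max(1, best$value)
  new("CalibrationResult", B = best$par[1], k = best$par[2],
      w = if (lz) best$par[3] else 0, value = best$value, trace = trace,
      converged = best$converged, nonIdentifiable = nonId)
}
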