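---
title: "Predicting cortical bone adaptation from voxel images: models and methods"
author: "BoneAdapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cortical bone adaptation from voxel images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoneAdapt)
```

## The problem

Longitudinal in vivo micro-CT of the mouse tibia shows cortical bone
continuously adding and removing tissue at its surfaces under ordinary cage
activity. BoneAdapt implements a mechanoregulation pipeline that predicts
this adaptation: it converts a grey-value volume into a voxel
micro-finite-element (micro-FE) model, computes a mechanical stimulus at
the bone surface under physiological load, and updates the image's tissue
mineral density (TMD) so that highly loaded surface regions gain mineral
and unloaded regions lose it. Comparing a predicted follow-up image with a
real (or synthetic) follow-up scan both calibrates the model's two free
parameters and quantifies its accuracy.

Because no public scan set accompanies the model, the package ships a
phantom generator producing tibia-like hollow-tube images, so every stage —
segmentation, FE solve, remodelling, calibration, validation metrics — is
exercised end-to-end on synthetic data with known ground truth.

## Segmentation with a transition zone

Images are binarised at a single subject-specific threshold: the midpoint
between the background and bone peaks of the grey-value histogram. Voxels
are bone iff strictly above the threshold. Around the threshold a
*transition zone* (TZ) is defined — on each side, the nearest histogram bin
whose count is at least twice the count of the threshold bin. Grey values
inside the TZ are ambiguous (partial-volume voxels mixing bone and
background attenuation) and are allowed to remodel in both directions.

Two numerical choices matter here:

* **Binning.** Integer-valued data use a bin width of 1 grey unit;
  continuous data use a Freedman–Diaconis-style width. Binning is fixed by
  rule so segmentation is reproducible.
* **Peak detection.** The background peak is the dominant histogram mode.
  The bone peak is the local maximum with the greatest *prominence*
  relative to the valley separating it from the dominant mode. Plain
  "second-highest local maximum" rules are fooled by counting noise riding
  on the background hump; prominence is not. A histogram with no second
  mode separated by a genuine valley is rejected as non-bimodal.

The threshold and TZ are computed once from a subject's baseline scan and
reused at all later time points, so longitudinal changes are never
confounded by re-segmentation.

## The micro-FE model

Every bone voxel becomes one linear 8-node hexahedral element with
homogeneous isotropic material (default E = 14.8 GPa, Poisson ratio 0.3,
the established values for cortical mouse bone). Because all elements are
identical cubes, a single 24×24 element stiffness matrix is shared, and the
global system is never assembled: the solver applies the stiffness
matrix-free, element by element, inside a Jacobi-preconditioned conjugate
gradient loop (default relative residual 1e-8, cap 1e5 iterations). SI
units are used internally (m, N, Pa); voxel spacing is converted from
micrometres at model build.

Boundary conditions follow the image axis convention (z longitudinal,
proximal at maximum z): the proximal node layer is fully constrained, and
the distal node layer is kinematically coupled to a rotation-fixed
reference point at the distal area centroid — realised as a single shared
translation vector for all distal nodes, which is also where loads are
applied. An eccentric cross-section under axial load therefore translates
without rotating, as the coupling demands.

Physiological loading scales linearly with body mass: 0.01355 N/g along
superior–inferior and 0.00289 N/g along anterior–posterior (the
medial–lateral component is zero and excluded by default, though the model
remains solvable along that axis). Unit 1-N loads are solved once per axis
and combined by superposition — applied to *displacements*, never to
strain-energy values, which are quadratic in strain.

### Stimulus extraction

Strains are evaluated at the 2×2×2 Gauss points, extrapolated to element
corners by the standard trilinear rule, and averaged over all elements
sharing a node. Two stimuli are supported:

* **SED** (strain energy density, Pa): the scalar ½ σ:ε is extrapolated.
  Nodal extrapolation can slightly undershoot zero near free surfaces;
  nodal SED is clamped at 0.
* **ε~maxprinc~** (maximum principal strain, microstrain): the six strain
  components are extrapolated and averaged first, and the largest
  eigenvalue of the averaged nodal tensor is taken last. The alternative
  order (eigenvalues at Gauss points, then extrapolation) does not commute
  with averaging and is not used.

Only surface nodes — nodes on at least one element face not shared with a
second element — carry the stimulus, since remodelling acts at bone
surfaces.

## The BRU update

The density update is node-centred: each surface node is the centre of a
*bone remodelling unit* (BRU) whose lattice vertices coincide with the
centres of the 8 voxels touching the node. Per time step (2 weeks), the
node's stimulus Θ commands a change in the BRU's mean TMD,

$$\Delta \mathrm{TMD} = B\,(\Theta - k),$$

with remodelling rate *B* (mg/cc per stimulus unit per step) and apposition
limit *k*: stimulus above *k* adds mineral, below *k* removes it, with the
same rate in both directions. An optional *lazy zone* of half-width *w*
about *k* (band edges inclusive) suppresses the response; *w* = 0
reproduces the base model exactly.

The commanded mean is reached by a single multiplicative factor applied to
a direction-dependent voxel subset: apposition scales the background and TZ
voxels, resorption scales the bone and TZ voxels (TZ voxels remodel both
ways). Voxels touched by several BRUs average the proposals they receive;
voxels with no incident surface node are never modified. Finally TMD is
clamped to [0, 1400] mg/cc — the update is open-loop, and the clamp keeps
images physically plausible.

Degenerate cases are handled explicitly:

* Pure-zero background makes multiplicative apposition ill-posed, so
  scaled-set values are floored at 1 mg/cc before scaling.
* A BRU whose scaled set is empty, or whose factor would be negative,
  proposes its unchanged values and is counted as *saturated*.
* The kernel accumulates proposal *differences*, so a BRU with zero
  response leaves its voxels bit-identical — `B = 0` or Θ ≡ *k* yields a
  voxel-identical output image, exactly.

## Calibration

*B* and *k* (optionally also *w*) are estimated from a baseline/follow-up
pair by least squares on the *sectional volumetric second moments*
(a bending-stiffness surrogate robust to slight longitudinal growth):
the occupied length is split into 10 sections, and per section
$I_{xx} = \sum (y-\bar y)^2\,v$ and $I_{yy} = \sum (x-\bar x)^2\,v$ are
taken over bone voxels about the section's own bone centroid (centring
makes the objective insensitive to residual in-plane translation). The
objective is the sum of squared per-section residuals between the
predicted and follow-up profiles.

The optimiser is a grid multistart — by default a 10×10 log-spaced lattice
over B ∈ [0.01, 1] mg/cc-Pa and k ∈ [0.1, 50] Pa, bracketing physiological
SED calibrations — followed by Nelder–Mead in *log-parameter space*, which
enforces B > 0 and k > 0 exactly through a smooth bijection rather than
penalties. Nelder–Mead is chosen because the objective is piecewise
constant at voxel-flip granularity: re-binarisation changes the moments
only when a voxel crosses the threshold, so finite-difference gradients
are uninformative. The full 100-start grid matters for the same reason —
coarser grids can strand the local search in near-zero plateaus of the
staircase objective. Within a one-step calibration the baseline mask is
fixed, so the elastic solution is computed once per problem and reused
exactly; each objective evaluation still performs the full BRU update,
re-binarisation and moment computation.

A pair with no detectable change drives *B* to its lower bound; the result
is then flagged non-identifiable (a zero-remodelling model fits as well as
the optimum).

## Morphometry and validation metrics

Densitometric indices — BV, TV, BV/TV, BMC, BMD, mean TMD — are reported
for the whole bone and a 40-compartment atlas (10 longitudinal sections,
distal to proximal, remainder slices assigned to the most proximal band;
4 angular sectors about the whole-bone centroid axis with half-open
boundaries on the 45° diagonals, so axisymmetric geometries split evenly).
TV is the volume enclosed by the periosteal surface, computed by
slice-wise 2D flood fill from the image border: cavities unreachable from
the border count toward TV, and an open (C-shaped) section whose lumen
leaks to the exterior contributes none, matching the standard
periosteal-contour convention.

Longitudinal comparisons first centre bone-volume centroids with an
integer-voxel translation (no rotation or resampling — upstream rigid
registration is assumed) and crop both images to the union bounding box.
Predictions are scored by:

* **Overlap ratio**: Jaccard index of the bone masks.
* **Remodelling sites**: voxels of the earlier mask's surface shell whose
  bone/background state crosses the threshold between time points —
  apposition for upward crossings, resorption for downward. Requiring a
  state change (not merely a grey change) makes sites binary and
  countable; this is an interpretation choice, recorded here.
* **Spatial match** = 100·|predicted ∩ experimental|/|predicted| and
  **prediction accuracy** = 100·|predicted ∩ experimental|/|experimental|,
  per direction, surface class (endosteal/periosteal, by slice-wise
  exterior flood fill) and section, with pooled whole-bone values and
  missing entries where a denominator is empty.

## The phantom generator

The generator emulates what the pipeline needs from a pre-aligned cortical
bone scan and nothing more: a tapered hollow tube along z (optionally with
an eccentric lumen), bone and background grey-value populations with
Gaussian jitter, Gaussian surface blur emulating the partial volume
effect, and a fixed seed making every volume a pure function of its spec.
Defaults: 40×40×120 voxels, outer radius tapering 12→10 voxels, 4-voxel
wall, bone 900 ± 30 mg/cc, background 100 ± 20 mg/cc, blur σ = 0.7 voxels.
With blur and noise disabled the image has exactly two grey values and the
threshold lands at their midpoint, giving exact-geometry oracles.

The default spacing is 40 µm — coarser than a typical 10.4 µm in vivo
protocol — so that the phantom's cross-section carries gram-scale
physiological loads at SED magnitudes of a few to a few hundred Pa, the
range where published apposition limits sit and where the default
calibration grid brackets the truth. What the phantom deliberately does
*not* reproduce: trabecular architecture, the fibula, growth plates,
anatomical cross-section shape, and registration error between time
points. Tests passing on phantoms therefore demonstrate the correctness of
the algorithmic machinery, not in vivo predictive accuracy.

## Problem sizes and numerical tolerances

The test-suite and acceptance experiments use phantom scales chosen to keep
each oracle sharp:

* FE closed forms use a 1×1×50 bar (exact axial solution at Poisson ratio
  0, where the single-element-through-thickness limit is exact; with
  ν > 0 the fully fixed proximal face adds Poisson constraint, and the
  uniform-strain SED check then uses the constrained modulus
  E(1−ν)/((1+ν)(1−2ν)) in place of E).
* Morphometry uses an annulus with ≥ 10 voxels across the wall, where
  voxel-centre sampling agrees with the continuum formula to well under
  2%.
* Calibration recovery uses 26×26×40 tubes (≈ 5000 elements, ≈ 5000
  surface nodes): large enough for sub-percent objective granularity,
  small enough that a 100-start calibration completes in about half a
  minute.
* The conjugate gradient solver runs at 1e-8 relative residual; solver
  comparisons (superposition vs direct solve) are asserted at 1e-5
  relative, reflecting two independent iterative solves.

## Known limitations

* Homogeneous isotropic elasticity; no grey-value-based modulus mapping.
* A single quasi-static peak-load case; no muscle forces, no load spectra.
* One stimulus at a time (SED or maximum principal strain); no combined
  or gradient-based stimuli.
* Calibration assumes one 2-week step between scans and global (not
  site-specific) parameters.
* The second-moment objective is piecewise constant, so calibrated
  parameters are identified up to voxel-flip granularity; the multistart
  design mitigates but cannot remove this.
* Rigid registration to a common reference frame is assumed done upstream;
  only integer-voxel centroid alignment is applied here.
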