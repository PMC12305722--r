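#' @import methods
NULL

#' Ellipsoidal lesion specification
#'
#' Describes a single lesion embedded in a digital phantom: an axis-aligned
#' ellipsoid given by its center, semi-axes and echogenicity contrast relative
#' to the background tissue.
#'
#' @slot center numeric(3), lesion center in world coordinates (mm).
#' @slot radii numeric(3), ellipsoid semi-axes (mm); a sphere when all equal.
#'   The emulated breast phantom carries tumors of 1.2--1.8 cm diameter,
#'   i.e. radii 6--9 mm.
#' @slot contrast numeric(1), relative echogenicity contrast in [-1, 1]
#'   added to the background level (negative = hypoechoic, the usual
#'   appearance of solid tumors in B-mode).
#' @exportClass LesionSpec
setClass("LesionSpec",
  slots = c(center = "numeric", radii = "numeric", contrast = "numeric"))

setValidity("LesionSpec", function(object) {
  msg <- character()
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    msg <- c(msg, "'center' must be a finite numeric vector of length 3")
  if (length(object@radii) != 3L || !all(is.finite(object@radii)) ||
      any(object@radii <= 0))
    msg <- c(msg, "'radii' must be three positive numbers (mm)")
  if (length(object@contrast) != 1L || !is.finite(object@contrast) ||
      abs(object@contrast) > 1)
    msg <- c(msg, "'contrast' must be a single number in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Digital tissue phantom
#'
#' A 3-D voxel grid of echogenicity in [0, 1] with an integer label grid
#' marking lesion membership (0 = background, k = lesion k).  Voxel k at
#' 0-based index \code{idx} has world-coordinate center
#' \code{origin + idx * spacing}.  Axis convention: x = rail/travel axis,
#' y = lateral, z = depth (the probe looks down +z).
#'
#' @slot grid 3-D numeric array of echogenicity in [0, 1].
#' @slot labels 3-D integer array, same shape as \code{grid}.
#' @slot spacing numeric(3), mm per voxel.
#' @slot origin numeric(3), world coordinate (mm) of the first voxel center.
#' @slot background numeric(1), background echogenicity level.
#' @slot lesions list of \linkS4class{LesionSpec}.
#' @exportClass Phantom
setClass("Phantom",
  slots = c(grid = "array", labels = "array", spacing = "numeric",
            origin = "numeric", background = "numeric", lesions = "list"))

setValidity("Phantom", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "'grid' must be a 3-D array")
  if (!identical(dim(object@grid), dim(object@labels)))
    msg <- c(msg, "'grid' and 'labels' must have identical shape")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be three positive numbers (mm/voxel)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "'origin' must be a numeric vector of length 3")
  if (any(object@grid < 0 | object@grid > 1))
    msg <- c(msg, "echogenicity values must lie in [0, 1]")
  if (length(object@lesions) &&
      !all(vapply(object@lesions, is, logical(1), "LesionSpec")))
    msg <- c(msg, "'lesions' must be a list of LesionSpec objects")
  k <- length(object@lesions)
  if (length(object@labels) && min(object@labels) < 0)
    msg <- c(msg, "labels must be non-negative")
  # upper bound checked only when lesion specs are carried (a phantom read
  # back from disk keeps its label grid but loses the spec list)
  if (k > 0L && length(object@labels) && max(object@labels) > k)
    msg <- c(msg, sprintf("labels must lie in 0..%d", k))
  if (length(msg)) msg else TRUE
})

#' Probe pose on the gantry
#'
#' The 3-DOF search variable: position along the linear rail plus gimbal
#' pitch and roll.  The lateral offset \code{y} exists for completeness but
#' is frozen at 0 — the gantry has a single actuated linear axis (one screw
#' rod); pitch and roll are the two servo angles.
#'
#' @slot x numeric(1), rail position (mm).
#' @slot y numeric(1), lateral offset (mm); always 0 in this artifact.
#' @slot pitch numeric(1), rotation about the lateral axis (degrees).
#' @slot roll numeric(1), rotation about the travel axis (degrees).
#' @exportClass ProbePose
setClass("ProbePose",
  slots = c(x = "numeric", y = "numeric", pitch = "numeric", roll = "numeric"))

setValidity("ProbePose", function(object) {
  vals <- c(object@x, object@y, object@pitch, object@roll)
  if (length(vals) != 4L || !all(is.finite(vals)))
    "x, y, pitch, roll must each be a single finite number"
  else TRUE
})

#' Gantry geometry and actuator constants
#'
#' Mechanical description of the simulated scanner: rail travel, gimbal pivot
#' height above the phantom surface, imaging-plane extent, and the actuator
#' constants of the NEMA-17 stepper (200 steps/rev) driving a TR8x2
#' trapezoidal screw (2 mm lead) plus two positioning servos.
#'
#' @slot railLength numeric(1), usable rail travel (mm).
#' @slot railY numeric(1), lateral world coordinate of the rail / central
#'   scan line (mm).
#' @slot pivotHeight numeric(1), gimbal pivot height above the phantom top
#'   surface z = 0 (mm).
#' @slot imageWidth numeric(1), lateral extent of the imaging plane (mm).
#' @slot imageDepth numeric(1), depth extent of the imaging plane (mm).
#' @slot sliceThickness numeric(1), elevation thickness of the acquired slab
#'   (mm), used by coverage analysis.
#' @slot stepsPerRev integer(1), stepper full steps per revolution.
#' @slot screwLead numeric(1), linear travel per screw revolution (mm).
#' @slot servoResolution numeric(1), servo angular quantum (degrees).
#' @exportClass GantryGeometry
setClass("GantryGeometry",
  slots = c(railLength = "numeric", railY = "numeric", pivotHeight = "numeric",
            imageWidth = "numeric", imageDepth = "numeric",
            sliceThickness = "numeric", stepsPerRev = "integer",
            screwLead = "numeric", servoResolution = "numeric"))

setValidity("GantryGeometry", function(object) {
  pos <- c(railLength = object@railLength, imageWidth = object@imageWidth,
           imageDepth = object@imageDepth, sliceThickness = object@sliceThickness,
           stepsPerRev = as.numeric(object@stepsPerRev),
           screwLead = object@screwLead, servoResolution = object@servoResolution)
  if (!all(is.finite(pos)) || any(pos <= 0))
    return("railLength, imageWidth, imageDepth, sliceThickness, stepsPerRev, screwLead and servoResolution must all be positive")
  if (!is.finite(object@railY) || !is.finite(object@pivotHeight) ||
      object@pivotHeight < 0)
    return("'railY' must be finite and 'pivotHeight' non-negative")
  TRUE
})

#' Synthesized B-mode slice
#'
#' A grayscale B-mode-like image on the imaging plane of a probe pose,
#' together with its ground-truth lesion label plane and an out-of-volume
#' flag for pixels sampled outside the phantom.  Matrices are stored with
#' rows running down the image (depth, v) and columns across it (lateral, u).
#'
#' @slot pixels numeric matrix, display intensities in [0, 255].
#' @slot labels integer matrix, lesion id per pixel (0 = background),
#'   sampled nearest-neighbor from the phantom label grid.
#' @slot outOfVolume logical matrix, TRUE where the sample point fell outside
#'   the phantom (such pixels carry background echogenicity and label 0).
#' @slot pixelSpacing numeric(1), mm per pixel (isotropic).
#' @slot pose the originating \linkS4class{ProbePose} (provenance).
#' @exportClass BModeImage
setClass("BModeImage",
  slots = c(pixels = "matrix", labels = "matrix", outOfVolume = "matrix",
            pixelSpacing = "numeric", pose = "ProbePose"))

setValidity("BModeImage", function(object) {
  msg <- character()
  if (!identical(dim(object@pixels), dim(object@labels)) ||
      !identical(dim(object@pixels), dim(object@outOfVolume)))
    msg <- c(msg, "'pixels', 'labels' and 'outOfVolume' must have identical shape")
  if (length(object@pixelSpacing) != 1L || object@pixelSpacing <= 0)
    msg <- c(msg, "'pixelSpacing' must be a single positive number (mm)")
  if (any(object@labels[object@outOfVolume] != 0L))
    msg <- c(msg, "out-of-volume pixels must carry label 0")
  if (length(msg)) msg else TRUE
})

#' Slice tumor-presence score
#'
#' @slot probability numeric(1) in [0, 1], likelihood of tumor presence in
#'   the slice.
#' @slot saliency a non-negative matrix of per-pixel evidence (the ideal
#'   class-activation map for the analytic scorer), or NULL.
#' @exportClass SliceScore
setClass("SliceScore", slots = c(probability = "numeric", saliency = "ANY"))

setValidity("SliceScore", function(object) {
  if (length(object@probability) != 1L || !is.finite(object@probability) ||
      object@probability < 0 || object@probability > 1)
    return("'probability' must be a single number in [0, 1]")
  if (!is.null(object@saliency) &&
      (!is.matrix(object@saliency) || any(object@saliency < 0)))
    return("'saliency' must be NULL or a non-negative matrix")
  TRUE
})

#' Scan-search configuration
#'
#' All parameters of the two-level search: the coarse linear step and station
#' count, the angular sweep geometry, and the refinement schedule.
#'
#' @slot xStart numeric(1), rail position of the first station (mm).
#' @slot slin0 numeric(1), initial linear step size (mm).
#' @slot nstep integer(1), number of stations in the first round.
#' @slot sTheta integer(1), angular index half-range: the sweep visits pitch
#'   and roll indices -sTheta..sTheta.
#' @slot alpha numeric(1), degrees per angular index (default 2, the
#'   gantry's fixed angular resolution).
#' @slot epsilon numeric(1), refinement stop threshold (mm): rounds continue
#'   while the step size is at least epsilon.
#' @slot thetaMax,phiMax numeric(1), pitch and roll bounds (degrees);
#'   alpha * sTheta must not exceed either.
#' @slot refineFactor numeric(1) > 1, step divisor per refinement round.
#' @slot tau numeric(1) in (0, 1), detection threshold on probability.
#' @slot pixelSpacing numeric(1), mm per pixel of the slices rendered during
#'   the search.
#' @exportClass ScanConfig
setClass("ScanConfig",
  slots = c(xStart = "numeric", slin0 = "numeric", nstep = "integer",
            sTheta = "integer", alpha = "numeric", epsilon = "numeric",
            thetaMax = "numeric", phiMax = "numeric", refineFactor = "numeric",
            tau = "numeric", pixelSpacing = "numeric"))

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (!(object@slin0 > object@epsilon && object@epsilon > 0))
    msg <- c(msg, "need slin0 > epsilon > 0")
  if (object@alpha <= 0 || object@sTheta < 0L)
    msg <- c(msg, "need alpha > 0 and sTheta >= 0")
  if (object@alpha * object@sTheta > min(object@thetaMax, object@phiMax) + 1e-9)
    msg <- c(msg, "alpha * sTheta must not exceed min(thetaMax, phiMax)")
  if (object@refineFactor <= 1)
    msg <- c(msg, "'refineFactor' must exceed 1")
  if (object@nstep < 1L)
    msg <- c(msg, "'nstep' must be at least 1")
  if (object@tau <= 0 || object@tau >= 1)
    msg <- c(msg, "'tau' must lie strictly in (0, 1)")
  if (object@pixelSpacing <= 0)
    msg <- c(msg, "'pixelSpacing' must be positive")
  if (object@xStart < 0)
    msg <- c(msg, "'xStart' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Trace of one zigzag angular sweep
#'
#' @slot d integer(1), direction indicator in {0, 1}; selects the traversal
#'   direction of the primary (pitch) index range.
#' @slot visited integer matrix with columns i, j: the pitch/roll indices in
#'   visit order; serpentine, so consecutive rows differ by one step in one
#'   index.
#' @slot scores numeric, probability per visited pose.
#' @slot aprob numeric(1), maximum score of the sweep.
#' @slot thetaPos,phiPos numeric(1), pitch and roll (degrees) attaining
#'   aprob (first visited on ties).
#' @exportClass SweepTrace
setClass("SweepTrace",
  slots = c(d = "integer", visited = "matrix", scores = "numeric",
            aprob = "numeric", thetaPos = "numeric", phiPos = "numeric"))

setValidity("SweepTrace", function(object) {
  msg <- character()
  if (nrow(object@visited) != length(object@scores))
    msg <- c(msg, "'visited' and 'scores' must have matching length")
  if (anyDuplicated(object@visited))
    msg <- c(msg, "each (i, j) pair must be visited exactly once")
  if (length(object@scores) && !isTRUE(all.equal(object@aprob, max(object@scores))))
    msg <- c(msg, "'aprob' must equal max(scores)")
  if (!object@d %in% c(0L, 1L))
    msg <- c(msg, "'d' must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Result of a scan search
#'
#' @slot mode "angular" or "linear".
#' @slot evaluations data.frame of every scored pose in evaluation order:
#'   columns order, round, station, x, pitch, roll, probability.
#' @slot lesionAreas numeric matrix (one row per evaluation, one column per
#'   lesion): in-volume area fraction each lesion occupies in that slice.
#' @slot rounds data.frame: round, step, nStations, bestScore.
#' @slot stationScores data.frame: round, station, x, lprob, aprob.
#' @slot Lmax \linkS4class{ProbePose} attaining the best probability (first
#'   visited on ties).
#' @slot Pmax numeric(1), the best probability.
#' @exportClass ScanResult
setClass("ScanResult",
  slots = c(mode = "character", evaluations = "data.frame",
            lesionAreas = "matrix", rounds = "data.frame",
            stationScores = "data.frame", Lmax = "ProbePose", Pmax = "numeric"))

setValidity("ScanResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("angular", "linear"))
    msg <- c(msg, "'mode' must be \"angular\" or \"linear\"")
  if (nrow(object@evaluations) &&
      !isTRUE(all.equal(object@Pmax, max(object@evaluations$probability))))
    msg <- c(msg, "'Pmax' must equal the maximum evaluated probability")
  if (nrow(object@rounds) > 1L && any(diff(object@rounds$step) >= 0))
    msg <- c(msg, "round step sizes must be strictly decreasing")
  if (length(msg)) msg else TRUE
})
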