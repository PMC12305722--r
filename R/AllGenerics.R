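#' @include AllClasses.R
NULL

#' Accessors for gimbalScan classes
#'
#' Slot access for the package's S4 containers.  Use these rather than
#' reaching into slots with \code{@}.
#'
#' @param object a gimbalScan S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("echoGrid", function(object) standardGeneric("echoGrid"))
#' @rdname accessors
#' @export
setGeneric("lesionLabels", function(object) standardGeneric("lesionLabels"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("phantomOrigin", function(object) standardGeneric("phantomOrigin"))
#' @rdname accessors
#' @export
setGeneric("lesionSpecs", function(object) standardGeneric("lesionSpecs"))
#' @rdname accessors
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setGeneric("labelPlane", function(object) standardGeneric("labelPlane"))
#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setGeneric("outOfVolume", function(object) standardGeneric("outOfVolume"))
#' @rdname accessors
#' @export
setGeneric("imagePose", function(object) standardGeneric("imagePose"))
#' @rdname accessors
#' @export
setGeneric("probability", function(object) standardGeneric("probability"))
#' @rdname accessors
#' @export
setGeneric("saliencyMap", function(object) standardGeneric("saliencyMap"))
#' @rdname accessors
#' @export
setGeneric("evaluations", function(object) standardGeneric("evaluations"))
#' @rdname accessors
#' @export
setGeneric("roundSummary", function(object) standardGeneric("roundSummary"))
#' @rdname accessors
#' @export
setGeneric("stationScores", function(object) standardGeneric("stationScores"))
#' @rdname accessors
#' @export
setGeneric("bestPose", function(object) standardGeneric("bestPose"))
#' @rdname accessors
#' @export
setGeneric("bestScore", function(object) standardGeneric("bestScore"))
#' @rdname accessors
#' @export
setGeneric("lesionAreaFractions", function(object) standardGeneric("lesionAreaFractions"))

setMethod("echoGrid", "Phantom", function(object) object@grid)
setMethod("lesionLabels", "Phantom", function(object) object@labels)
setMethod("voxelSpacing", "Phantom", function(object) object@spacing)
setMethod("phantomOrigin", "Phantom", function(object) object@origin)
setMethod("lesionSpecs", "Phantom", function(object) object@lesions)

setMethod("imagePixels", "BModeImage", function(object) object@pixels)
setMethod("labelPlane", "BModeImage", function(object) object@labels)
setMethod("lesionMask", "BModeImage", function(object) object@labels > 0L)
setMethod("outOfVolume", "BModeImage", function(object) object@outOfVolume)
setMethod("imagePose", "BModeImage", function(object) object@pose)
setMethod("voxelSpacing", "BModeImage", function(object) object@pixelSpacing)

setMethod("probability", "SliceScore", function(object) object@probability)
setMethod("saliencyMap", "SliceScore", function(object) object@saliency)

setMethod("evaluations", "ScanResult", function(object) object@evaluations)
setMethod("roundSummary", "ScanResult", function(object) object@rounds)
setMethod("stationScores", "ScanResult", function(object) object@stationScores)
setMethod("bestPose", "ScanResult", function(object) object@Lmax)
setMethod("bestScore", "ScanResult", function(object) object@Pmax)
setMethod("lesionAreaFractions", "ScanResult", function(object) object@lesionAreas)

setMethod("show", "LesionSpec", function(object) {
  cat(sprintf("LesionSpec: center (%s) mm, radii (%s) mm, contrast %+0.2f\n",
              paste(format(object@center), collapse = ", "),
              paste(format(object@radii), collapse = ", "),
              object@contrast))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@grid)
  cat("Phantom\n")
  cat(sprintf("  grid    : %d x %d x %d voxels (%.4g MB)\n", d[1], d[2], d[3],
              utils::object.size(object@grid) / 2^20))
  cat(sprintf("  spacing : %s mm/voxel\n",
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  extent  : %s mm\n",
              paste(format(d * object@spacing), collapse = " x ")))
  cat(sprintf("  lesions : %d (labeled voxels: %d)\n", length(object@lesions),
              sum(object@labels > 0L)))
})

setMethod("show", "ProbePose", function(object) {
  cat(sprintf("ProbePose: x = %.3f mm, pitch = %.2f deg, roll = %.2f deg\n",
              object@x, object@pitch, object@roll))
})

setMethod("show", "GantryGeometry", function(object) {
  cat("GantryGeometry\n")
  cat(sprintf("  rail    : %.0f mm travel at y = %.0f mm, pivot %.0f mm above surface\n",
              object@railLength, object@railY, object@pivotHeight))
  cat(sprintf("  imaging : %.0f mm wide x %.0f mm deep, slab %.1f mm\n",
              object@imageWidth, object@imageDepth, object@sliceThickness))
  cat(sprintf("  motors  : stepper %d steps/rev on %.1f mm lead (%.4f mm/step); servo %.1f deg\n",
              object@stepsPerRev, object@screwLead,
              object@screwLead / object@stepsPerRev, object@servoResolution))
})

setMethod("show", "BModeImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BModeImage: %d x %d px at %.2f mm/px; %d lesion px, %d out-of-volume px\n",
              d[1], d[2], object@pixelSpacing, sum(object@labels > 0L),
              sum(object@outOfVolume)))
  cat("  pose: "); show(object@pose)
})

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig\n")
  cat(sprintf("  linear : start %.1f mm, step %.1f mm, %d stations; refine /%.1f until < %.2f mm\n",
              object@xStart, object@slin0, object@nstep, object@refineFactor,
              object@epsilon))
  cat(sprintf("  angular: +/- %d x %.1f deg (%d poses/station), bounds %.0f/%.0f deg\n",
              object@sTheta, object@alpha, (2L * object@sTheta + 1L)^2,
              object@thetaMax, object@phiMax))
  cat(sprintf("  scoring: tau = %.2f, pixel spacing %.2f mm\n",
              object@tau, object@pixelSpacing))
})

setMethod("show", "SweepTrace", function(object) {
  cat(sprintf("SweepTrace: d = %d, %d poses, aprob = %.4f at (pitch %.1f, roll %.1f) deg\n",
              object@d, nrow(object@visited), object@aprob, object@thetaPos,
              object@phiPos))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s mode)\n", object@mode))
  cat(sprintf("  evaluations: %d over %d rounds\n", nrow(object@evaluations),
              nrow(object@rounds)))
  cat(sprintf("  Pmax = %.4f at ", object@Pmax)); show(object@Lmax)
})
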