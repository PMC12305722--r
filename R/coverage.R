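#' Phantom coverage of an acquired pose set
#'
#' A voxel counts as covered when its center lies within half the slice
#' thickness of at least one acquired imaging plane and projects inside that
#' plane's image rectangle.  Tumor coverage is evaluated on the phantom's
#' actual lesion voxels; total coverage may be evaluated on a coarser sample
#' grid (\code{resolution}) to keep the voxel-plane test affordable on
#' large phantoms.
#'
#' @param poses a \linkS4class{ScanResult} or a data.frame with columns x,
#'   pitch, roll; duplicate poses are collapsed.
#' @param geometry a \linkS4class{GantryGeometry}.
#' @param phantom a \linkS4class{Phantom}.
#' @param resolution sample-grid spacing (mm) for the total-coverage map;
#'   NULL uses the phantom's own voxel centers.
#' @return List with \code{hits} (logical array on the sample grid),
#'   \code{gridCoords} (axis coordinate vectors of that grid),
#'   \code{totalCoverage}, \code{tumorCoverage} (covered lesion voxels /
#'   lesion voxels, NA when the phantom has none) and \code{perLesion}.
#' @examples
#' fx <- makeFixture("single_centered", seed = 1)
#' dense <- data.frame(x = seq(70, 90, by = 2), pitch = 0, roll = 0)
#' coverageMap(dense, fx$geometry, fx$phantom, resolution = 4)$tumorCoverage
#' @export
coverageMap <- function(poses, geometry, phantom, resolution = NULL) {
  if (is(poses, "ScanResult")) poses <- visitedLattice(poses)
  stopifnot(is.data.frame(poses), nrow(poses) >= 1L)
  key <- sprintf("%.6f|%.4f|%.4f", poses$x, poses$pitch, poses$roll)
  poses <- poses[!duplicated(key), , drop = FALSE]

  shape <- dim(phantom@grid)
  full <- .axisCoords(shape, phantom@spacing, phantom@origin)
  gridCoords <- if (is.null(resolution)) full else
    lapply(1:3, function(ax) .seqStep(full[[ax]][1],
                                      full[[ax]][length(full[[ax]])],
                                      resolution))
  nAx <- vapply(gridCoords, length, integer(1))
  V <- cbind(rep(gridCoords[[1]], times = nAx[2] * nAx[3]),
             rep(rep(gridCoords[[2]], each = nAx[1]), times = nAx[3]),
             rep(gridCoords[[3]], each = nAx[1] * nAx[2]))

  lesIdx <- which(phantom@labels > 0L)
  if (length(lesIdx)) {
    sub <- arrayInd(lesIdx, shape)
    L <- cbind(full[[1]][sub[, 1]], full[[2]][sub[, 2]], full[[3]][sub[, 3]])
    lesId <- phantom@labels[lesIdx]
  }

  halfT <- geometry@sliceThickness / 2
  halfW <- geometry@imageWidth / 2
  tol <- 1e-9
  hitTest <- function(P, plane) {
    W <- P %*% cbind(plane$n, plane$u, plane$v)
    off <- c(sum(plane$origin * plane$n), sum(plane$origin * plane$u),
             sum(plane$origin * plane$v))
    abs(W[, 1] - off[1]) <= halfT + tol &
      abs(W[, 2] - off[2]) <= halfW + tol &
      W[, 3] - off[3] >= -tol & W[, 3] - off[3] <= geometry@imageDepth + tol
  }

  hits <- rep(FALSE, nrow(V))
  lesHits <- if (length(lesIdx)) rep(FALSE, length(lesIdx)) else logical()
  for (r in seq_len(nrow(poses))) {
    plane <- poseToPlane(probePose(poses$x[r], pitch = poses$pitch[r],
                                   roll = poses$roll[r]), geometry)
    todo <- !hits
    if (any(todo)) hits[todo] <- hitTest(V[todo, , drop = FALSE], plane)
    if (length(lesIdx)) {
      todoL <- !lesHits
      if (any(todoL)) lesHits[todoL] <- hitTest(L[todoL, , drop = FALSE], plane)
    }
  }

  perLesion <- if (length(lesIdx)) {
    vapply(seq_along(phantom@lesions), function(k) {
      sel <- lesId == k
      if (any(sel)) mean(lesHits[sel]) else NA_real_
    }, numeric(1))
  } else numeric()

  list(hits = array(hits, dim = nAx), gridCoords = gridCoords,
       totalCoverage = mean(hits),
       tumorCoverage = if (length(lesIdx)) mean(lesHits) else NA_real_,
       perLesion = perLesion)
}

#' Write a coverage hit map as NIfTI
#'
#' @param coverage list from \code{\link{coverageMap}}.
#' @param file output path (.nii or .nii.gz).
#' @param spacing voxel spacing of the coverage grid (mm); inferred from the
#'   grid coordinates when NULL.
#' @return The path, invisibly.
#' @export
writeCoverageNifti <- function(coverage, file, spacing = NULL) {
  if (is.null(spacing))
    spacing <- vapply(coverage$gridCoords, function(co)
      if (length(co) > 1L) co[2] - co[1] else 1, numeric(1))
  im <- RNifti::asNifti(coverage$hits * 1L, internal = FALSE)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, file, datatype = "uint8")
  invisible(file)
}
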