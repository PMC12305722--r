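#' Create a lesion specification
#'
#' @param center numeric(3), lesion center in world coordinates (mm).
#' @param radii numeric(3) or numeric(1) (sphere), ellipsoid semi-axes (mm).
#' @param contrast echogenicity contrast relative to background, in [-1, 1];
#'   negative for the hypoechoic appearance typical of solid tumors.
#' @return A \linkS4class{LesionSpec}.
#' @examples
#' lesionSpec(c(80, 60, 30), 7)          # 14 mm sphere
#' lesionSpec(c(40, 60, 30), c(6, 9, 6)) # ellipsoid
#' @export
lesionSpec <- function(center, radii, contrast = -0.25) {
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  new("LesionSpec", center = as.numeric(center), radii = as.numeric(radii),
      contrast = as.numeric(contrast))
}

# [1,2,1]/4 smoothing along each array axis with replicated edges; applied
# `passes` times.  Gives the background texture a short correlation length
# without pulling in an image-filtering dependency for a 3-D kernel.
.smooth3d <- function(a, passes = 2L) {
  dims <- dim(a)
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      n <- dims[ax]
      if (n < 2L) next
      lo <- pmax(seq_len(n) - 1L, 1L)
      hi <- pmin(seq_len(n) + 1L, n)
      a <- switch(ax,
        (a[lo, , , drop = FALSE] + 2 * a + a[hi, , , drop = FALSE]) / 4,
        (a[, lo, , drop = FALSE] + 2 * a + a[, hi, , drop = FALSE]) / 4,
        (a[, , lo, drop = FALSE] + 2 * a + a[, , hi, drop = FALSE]) / 4)
    }
  }
  a
}

# 0-based voxel-center world coordinates along each axis
.axisCoords <- function(shape, spacing, origin) {
  lapply(1:3, function(ax) origin[ax] + (seq_len(shape[ax]) - 1) * spacing[ax])
}

#' Build a digital tissue phantom
#'
#' Generates a voxelized tissue block with embedded ellipsoidal lesions,
#' emulating a commercial breast phantom (16 x 12 cm footprint with tumors of
#' 1.2--1.8 cm diameter).  A voxel belongs to lesion k exactly when its
#' center satisfies the ellipsoid inequality for that lesion (voxel-center
#' inclusion; no partial-volume blending).  A low-amplitude smoothed Gaussian
#' texture is added so that slices are not piecewise constant; the result is
#' deterministic for a fixed \code{textureSeed}.
#'
#' @param extent numeric(3), physical size (mm); default 160 x 120 x 60 (the
#'   emulated phantom footprint; the 60 mm depth is a package default, the
#'   physical phantom's thickness being unspecified).
#' @param spacing numeric(3) or numeric(1), mm per voxel.
#' @param background background echogenicity level in [0, 1].
#' @param lesions list of \code{\link{lesionSpec}} objects; may be empty.
#' @param textureSeed integer seed for the background texture.
#' @param textureAmplitude standard deviation of the texture before
#'   smoothing, relative units (default 0.05).
#' @param origin numeric(3), world coordinate of the first voxel center.
#' @return A \linkS4class{Phantom}.
#' @examples
#' ph <- buildPhantom(extent = c(40, 40, 30), spacing = 2,
#'                    lesions = list(lesionSpec(c(20, 20, 15), 6)),
#'                    textureSeed = 1)
#' ph
#' @export
buildPhantom <- function(extent = c(160, 120, 60), spacing = c(1, 1, 1),
                         background = 0.35, lesions = list(),
                         textureSeed = 1L, textureAmplitude = 0.05,
                         origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  extent <- as.numeric(extent); spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(extent) == 3L, all(extent > 0), all(spacing > 0),
            background >= 0, background <= 1, textureAmplitude >= 0)
  shape <- as.integer(round(extent / spacing))
  if (any(shape < 2L))
    stop("extent/spacing must yield at least 2 voxels per axis")
  lo <- origin - spacing / 2
  hi <- origin + (shape - 0.5) * spacing
  for (k in seq_along(lesions)) {
    ls <- lesions[[k]]
    validObject(ls)
    if (any(ls@center - ls@radii < lo) || any(ls@center + ls@radii > hi))
      stop(sprintf("lesion %d does not lie fully inside the phantom extent", k))
  }

  grid <- array(background, dim = shape)
  labels <- array(0L, dim = shape)
  co <- .axisCoords(shape, spacing, origin)
  for (k in seq_along(lesions)) {
    ls <- lesions[[k]]
    q <- outer(outer(((co[[1]] - ls@center[1]) / ls@radii[1])^2,
                     ((co[[2]] - ls@center[2]) / ls@radii[2])^2, "+"),
               ((co[[3]] - ls@center[3]) / ls@radii[3])^2, "+")
    inside <- q <= 1
    if (any(labels[inside] != 0L))
      stop(sprintf("lesion %d overlaps an earlier lesion", k))
    labels[inside] <- k
    grid[inside] <- min(max(background + ls@contrast, 0), 1)
  }
  if (textureAmplitude > 0) {
    tex <- .withSeed(as.integer(textureSeed), {
      .smooth3d(array(stats::rnorm(prod(shape), sd = textureAmplitude),
                      dim = shape))
    })
    grid <- pmin(pmax(grid + tex, 0), 1)
  }
  new("Phantom", grid = grid, labels = labels, spacing = spacing,
      origin = origin, background = background, lesions = lesions)
}

#' Two-tumor validation layout
#'
#' Builds the lesion layout used for linear-versus-angular validation: tumor
#' 1 centered on the central scan line and tumor 2 displaced laterally by
#' \code{offAxisOffset}.  With the default 60 mm imaging width, an offset
#' exceeding \code{(imageWidth + offAxisDiameter) / 2} places tumor 2 wholly
#' outside the slab swept by zero-angle slices, so only angled acquisitions
#' can reach it.
#'
#' @param onAxisDiameter,offAxisDiameter tumor diameters (mm); the emulated
#'   phantom's tumors span 12--18 mm.
#' @param offAxisOffset lateral displacement of tumor 2 from the scan line
#'   (mm); 0 gives the degenerate both-on-line control.
#' @param extent phantom extent (mm) used to validate placement.
#' @param scanLineY lateral coordinate of the central scan line (mm).
#' @param xCenter rail coordinate of both tumor centers (mm).
#' @param depth depth of both tumor centers (mm).
#' @param contrast echogenicity contrast of both tumors.
#' @param diameterRange admissible diameter interval (mm).
#' @return List of two \linkS4class{LesionSpec} objects.
#' @examples
#' twoTumorLayout(14, 14, 40)
#' twoTumorLayout(12, 18, 30)  # radii 6 and 9 mm
#' @export
twoTumorLayout <- function(onAxisDiameter = 14, offAxisDiameter = 14,
                           offAxisOffset = 40, extent = c(160, 120, 60),
                           scanLineY = extent[2] / 2, xCenter = extent[1] / 2,
                           depth = extent[3] / 2, contrast = -0.25,
                           diameterRange = c(12, 18)) {
  d <- c(onAxisDiameter, offAxisDiameter)
  if (any(d < diameterRange[1] - 1e-9) || any(d > diameterRange[2] + 1e-9))
    stop(sprintf("tumor diameters must lie within [%g, %g] mm",
                 diameterRange[1], diameterRange[2]))
  r2 <- offAxisDiameter / 2
  y2 <- scanLineY + offAxisOffset
  if (y2 - r2 < 0 || y2 + r2 > extent[2])
    stop("offAxisOffset pushes tumor 2 outside the phantom")
  list(
    lesionSpec(c(xCenter, scanLineY, depth), onAxisDiameter / 2, contrast),
    lesionSpec(c(xCenter, y2, depth), r2, contrast)
  )
}

#' Write / read a phantom as NIfTI
#'
#' The echogenicity grid and the label grid are written as two NIfTI files
#' with voxel spacing in the header.  Lesion specifications are not part of
#' the NIfTI model, so a phantom read back carries an empty spec list (its
#' label grid is intact).
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param gridFile,labelsFile output/input paths (.nii or .nii.gz).
#' @param background background level to record on the reread phantom.
#' @return \code{writePhantom} returns the two paths invisibly;
#'   \code{readPhantom} returns a \linkS4class{Phantom}.
#' @export
writePhantom <- function(phantom, gridFile, labelsFile) {
  stopifnot(is(phantom, "Phantom"))
  g <- RNifti::asNifti(phantom@grid, internal = FALSE)
  RNifti::pixdim(g) <- phantom@spacing
  RNifti::writeNifti(g, gridFile)
  l <- RNifti::asNifti(phantom@labels + 0L, internal = FALSE)
  RNifti::pixdim(l) <- phantom@spacing
  RNifti::writeNifti(l, labelsFile, datatype = "int16")
  invisible(c(gridFile, labelsFile))
}

#' @rdname writePhantom
#' @export
readPhantom <- function(gridFile, labelsFile, background = NULL) {
  img <- RNifti::readNifti(gridFile)
  lab <- RNifti::readNifti(labelsFile)
  spacing <- RNifti::pixdim(img)[1:3]
  grid <- array(as.numeric(img), dim = dim(img))
  labels <- array(as.integer(lab), dim = dim(lab))
  if (is.null(background)) background <- stats::median(grid[labels == 0L])
  new("Phantom", grid = grid, labels = labels, spacing = as.numeric(spacing),
      origin = c(0, 0, 0), background = background, lesions = list())
}
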