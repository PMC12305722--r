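#' Imaging (rendering) parameters
#'
#' Display-chain parameters of the B-mode synthesizer.
#'
#' @param attenuation depth attenuation coefficient (per mm) applied as
#'   \code{exp(-attenuation * depth)}; 0 disables attenuation.
#' @param gain log-compression gain g: display intensity is proportional to
#'   \code{log(1 + g * I)}, the conventional display mapping.
#' @param speckle logical; multiply by unit-mean Rayleigh speckle (the
#'   first-order statistic of fully developed speckle).
#' @return A list of class "imagingParams".
#' @export
imagingParams <- function(attenuation = 0.01, gain = 50, speckle = TRUE) {
  stopifnot(attenuation >= 0, gain > 0, is.logical(speckle))
  structure(list(attenuation = attenuation, gain = gain, speckle = speckle),
            class = "imagingParams")
}

#' Extract an oblique slice from a phantom
#'
#' Resamples the phantom on the imaging plane of a pose: echogenicity by
#' trilinear interpolation, lesion labels by nearest neighbor.  Pixels whose
#' sample point falls outside the phantom get the background echogenicity
#' and label 0 and are flagged in \code{outOfVolume}.  Matrices are laid out
#' with rows running down the beam (depth) and columns across it (lateral).
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param pose a \linkS4class{ProbePose}.
#' @param geometry a \linkS4class{GantryGeometry}.
#' @param pixelSpacing mm per pixel (isotropic), > 0.
#' @return List with \code{echo}, \code{labels}, \code{outOfVolume} matrices,
#'   \code{depth} (mm per row along the beam), \code{pixelSpacing} and
#'   \code{pose}.
#' @export
extractSlice <- function(phantom, pose, geometry, pixelSpacing = 1) {
  stopifnot(is(phantom, "Phantom"), pixelSpacing > 0)
  pl <- poseToPlane(pose, geometry)
  nu <- floor(geometry@imageWidth / pixelSpacing + 1e-9) + 1L
  nv <- floor(geometry@imageDepth / pixelSpacing + 1e-9) + 1L
  if (nu < 2L || nv < 2L) stop("degenerate imaging plane: too few pixels")
  uOff <- (seq_len(nu) - 1) * pixelSpacing - geometry@imageWidth / 2
  vOff <- (seq_len(nv) - 1) * pixelSpacing

  dims <- dim(phantom@grid)
  sp <- phantom@spacing; o <- phantom@origin
  # continuous 0-based voxel index of each pixel center; rows = v, cols = u
  ix <- (outer(vOff * pl$v[1], uOff * pl$u[1], "+") + pl$origin[1] - o[1]) / sp[1]
  iy <- (outer(vOff * pl$v[2], uOff * pl$u[2], "+") + pl$origin[2] - o[2]) / sp[2]
  iz <- (outer(vOff * pl$v[3], uOff * pl$u[3], "+") + pl$origin[3] - o[3]) / sp[3]

  tol <- 1e-9
  inVol <- ix >= -tol & ix <= dims[1] - 1 + tol &
           iy >= -tol & iy <= dims[2] - 1 + tol &
           iz >= -tol & iz <= dims[3] - 1 + tol

  echo <- matrix(phantom@background, nv, nu)
  labs <- matrix(0L, nv, nu)
  if (any(inVol)) {
    cx <- pmin(pmax(ix[inVol], 0), dims[1] - 1)
    cy <- pmin(pmax(iy[inVol], 0), dims[2] - 1)
    cz <- pmin(pmax(iz[inVol], 0), dims[3] - 1)
    i0 <- pmin(floor(cx), dims[1] - 2); fx <- cx - i0
    j0 <- pmin(floor(cy), dims[2] - 2); fy <- cy - j0
    k0 <- pmin(floor(cz), dims[3] - 2); fz <- cz - k0
    g <- phantom@grid
    base <- i0 + dims[1] * (j0 + dims[2] * k0) + 1
    dX <- 1; dY <- dims[1]; dZ <- dims[1] * dims[2]
    val <-
      g[base]                  * (1 - fx) * (1 - fy) * (1 - fz) +
      g[base + dX]             * fx       * (1 - fy) * (1 - fz) +
      g[base + dY]             * (1 - fx) * fy       * (1 - fz) +
      g[base + dX + dY]        * fx       * fy       * (1 - fz) +
      g[base + dZ]             * (1 - fx) * (1 - fy) * fz +
      g[base + dX + dZ]        * fx       * (1 - fy) * fz +
      g[base + dY + dZ]        * (1 - fx) * fy       * fz +
      g[base + dX + dY + dZ]   * fx       * fy       * fz
    echo[inVol] <- val
    nn <- round(cx) + dims[1] * (round(cy) + dims[2] * round(cz)) + 1
    labs[inVol] <- phantom@labels[nn]
  }
  list(echo = echo, labels = labs, outOfVolume = !inVol,
       depth = vOff, pixelSpacing = pixelSpacing, pose = pose)
}

#' Render a B-mode image from an extracted slice
#'
#' Applies the display chain to the echogenicity plane: depth attenuation
#' \code{exp(-attenuation * depth)}, multiplicative unit-mean Rayleigh
#' speckle (seeded, hence reproducible), log compression
#' \code{log(1 + gain * I) / log(1 + gain)} and scaling to [0, 255].
#'
#' @param slice list from \code{\link{extractSlice}}.
#' @param imaging an \code{\link{imagingParams}} list.
#' @param seed integer seed for the speckle field.
#' @return A \linkS4class{BModeImage}.
#' @export
renderBMode <- function(slice, imaging = imagingParams(), seed = 0L) {
  I <- slice$echo * exp(-imaging$attenuation * slice$depth)  # recycles by row
  if (imaging$speckle) {
    spk <- .withSeed(as.integer(seed),
                     matrix(.rrayleighUnit(length(I)), nrow(I), ncol(I)))
    I <- I * spk
  }
  px <- pmin(255 * log1p(imaging$gain * I) / log1p(imaging$gain), 255)
  new("BModeImage", pixels = px, labels = slice$labels,
      outOfVolume = slice$outOfVolume, pixelSpacing = slice$pixelSpacing,
      pose = slice$pose)
}

#' Acquire a B-mode image at a pose
#'
#' Convenience wrapper: extract the slice and render it, with the speckle
#' seed derived from the global seed and the pose's actuator-lattice indices,
#' so a pose's image does not depend on visit order.
#'
#' @inheritParams extractSlice
#' @param imaging an \code{\link{imagingParams}} list.
#' @param seed global integer seed.
#' @return A \linkS4class{BModeImage}.
#' @examples
#' ph <- buildPhantom(extent = c(40, 40, 30), spacing = 2,
#'                    lesions = list(lesionSpec(c(20, 20, 15), 6)),
#'                    textureSeed = 1)
#' geo <- gantryGeometry(railLength = 40, railY = 20, imageWidth = 30,
#'                       imageDepth = 30)
#' acquireBMode(ph, probePose(20), geo, pixelSpacing = 2, seed = 1)
#' @export
acquireBMode <- function(phantom, pose, geometry, pixelSpacing = 1,
                         imaging = imagingParams(), seed = 0L) {
  sl <- extractSlice(phantom, pose, geometry, pixelSpacing)
  renderBMode(sl, imaging,
              seed = .poseSeed(seed, pose@x, pose@pitch, pose@roll))
}

#' Write a B-mode image (and mask) as 8-bit grayscale PNG
#'
#' @param image a \linkS4class{BModeImage}.
#' @param file PNG path for the pixels.
#' @param maskFile optional PNG path for the 0/255 lesion mask.
#' @param sidecar optional JSON path recording pose and spacing.
#' @return Invisibly, the paths written.
#' @export
writeBModePNG <- function(image, file, maskFile = NULL, sidecar = NULL) {
  stopifnot(is(image, "BModeImage"))
  png::writePNG(image@pixels / 255, file)
  out <- file
  if (!is.null(maskFile)) {
    png::writePNG((image@labels > 0L) * 1, maskFile)
    out <- c(out, maskFile)
  }
  if (!is.null(sidecar)) {
    p <- image@pose
    jsonlite::write_json(
      list(pose = list(x = p@x, y = p@y, pitch = p@pitch, roll = p@roll),
           pixel_spacing = image@pixelSpacing, shape = dim(image@pixels)),
      sidecar, auto_unbox = TRUE, digits = NA)
    out <- c(out, sidecar)
  }
  invisible(out)
}
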