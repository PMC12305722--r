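# Shared helpers: tiny phantoms, canned scorers, random masks.

# Small sphere phantom, texture optional; defaults keep tests fast.
tinySpherePhantom <- function(radius = 6, extent = c(40, 40, 30), spacing = 2,
                              center = extent / 2, contrast = -0.25,
                              textureAmplitude = 0, seed = 1L) {
  buildPhantom(extent = extent, spacing = spacing,
               lesions = list(lesionSpec(center, radius, contrast)),
               textureSeed = seed, textureAmplitude = textureAmplitude)
}

tinyGeometry <- function(extent = c(40, 40, 30), imageWidth = 32,
                         imageDepth = 28, pivotHeight = 10)
  gantryGeometry(railLength = extent[1], railY = extent[2] / 2,
                 pivotHeight = pivotHeight, imageWidth = imageWidth,
                 imageDepth = imageDepth, sliceThickness = 2)

# A scorer that looks only at the pose, for exercising search logic with
# hand-chosen score fields.
poseScorer <- function(f) function(image) f(imagePose(image))

# Synthetic BModeImage with a given number of lesion pixels.
syntheticImage <- function(nLesion, n = 50L, nOov = 0L) {
  labels <- matrix(0L, n, n)
  if (nLesion > 0) labels[seq_len(nLesion)] <- 1L
  oov <- matrix(FALSE, n, n)
  if (nOov > 0) oov[n * n - seq_len(nOov) + 1L] <- TRUE
  labels[oov] <- 0L
  new("BModeImage", pixels = matrix(128, n, n), labels = labels,
      outOfVolume = oov, pixelSpacing = 1, pose = probePose(0))
}

randomMask <- function(n = 12L, p = 0.3) matrix(stats::runif(n * n) < p, n, n)
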