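test_that("a lattice-aligned zero-angle slice equals the voxel slice exactly", {
  ph <- tinySpherePhantom(textureAmplitude = 0.05)
  geo <- tinyGeometry()                      # width 32, depth 28, spacing 2 grid
  sl <- extractSlice(ph, probePose(20), geo, pixelSpacing = 2)
  expect_false(any(sl$outOfVolume))
  # plane at x = 20 is voxel plane ix = 10 (0-based); rows = depth, cols = lateral
  want <- t(echoGrid(ph)[11, 3:19, 1:15])
  dimnames(want) <- NULL
  expect_identical(sl$echo, want)
  wantLab <- t(lesionLabels(ph)[11, 3:19, 1:15])
  dimnames(wantLab) <- NULL
  expect_identical(sl$labels, matrix(as.integer(wantLab), nrow(wantLab)))
})

test_that("label plane agrees with an independent nearest-neighbor resampling", {
  ph <- tinySpherePhantom(textureAmplitude = 0.05)
  geo <- tinyGeometry()
  pose <- probePose(17.3, pitch = 7, roll = -4)
  sl <- extractSlice(ph, pose, geo, pixelSpacing = 1.5)
  pl <- poseToPlane(pose, geo)
  nu <- ncol(sl$labels); nv <- nrow(sl$labels)
  uOff <- (seq_len(nu) - 1) * 1.5 - geo@imageWidth / 2
  vOff <- (seq_len(nv) - 1) * 1.5
  lab <- lesionLabels(ph)
  for (iv in seq(1, nv, by = 3)) for (iu in seq(1, nu, by = 3)) {
    p <- pl$origin + uOff[iu] * pl$u + vOff[iv] * pl$v
    cont <- (p - phantomOrigin(ph)) / voxelSpacing(ph)
    inVol <- all(cont >= -1e-9 & cont <= dim(lab) - 1 + 1e-9)
    expect_identical(sl$outOfVolume[iv, iu], !inVol)
    idx <- round(pmin(pmax(cont, 0), dim(lab) - 1))
    want <- if (inVol) lab[idx[1] + 1, idx[2] + 1, idx[3] + 1] else 0L
    expect_identical(sl$labels[iv, iu], want)
  }
})

test_that("an oblique plane through a sphere center carries a great-circle cross-section", {
  r <- 9
  ph <- buildPhantom(extent = c(60, 60, 60), spacing = 1,
                     lesions = list(lesionSpec(c(30, 30, 30), r)),
                     textureSeed = 1, textureAmplitude = 0)
  geo <- gantryGeometry(railLength = 60, railY = 30, pivotHeight = 10,
                        imageWidth = 60, imageDepth = 60)
  theta <- 10
  # choose the station so the pitched plane passes exactly through the center
  x0 <- 30 - (30 + geo@pivotHeight) * tan(theta * pi / 180)
  sl <- extractSlice(ph, probePose(x0, pitch = theta), geo, pixelSpacing = 1)
  area <- sum(sl$labels > 0L) * 1^2
  expect_gt(area, 0.93 * pi * r^2)
  expect_lt(area, 1.07 * pi * r^2)
})

test_that("rendering without attenuation or speckle is a monotone rescaling of echogenicity", {
  ph <- tinySpherePhantom(textureAmplitude = 0.05)
  sl <- extractSlice(ph, probePose(20), tinyGeometry(), pixelSpacing = 2)
  img <- renderBMode(sl, imagingParams(attenuation = 0, speckle = FALSE))
  o <- order(sl$echo)
  expect_true(all(diff(imagePixels(img)[o]) >= 0))
  # strictly monotone where echo differs
  expect_identical(rank(imagePixels(img)), rank(sl$echo))
})

test_that("rendering is bit-identical for a fixed seed and differs across seeds", {
  ph <- tinySpherePhantom(textureAmplitude = 0.05)
  sl <- extractSlice(ph, probePose(20), tinyGeometry(), pixelSpacing = 2)
  a <- renderBMode(sl, seed = 9L)
  b <- renderBMode(sl, seed = 9L)
  expect_identical(imagePixels(a), imagePixels(b))
  expect_false(identical(imagePixels(a),
                         imagePixels(renderBMode(sl, seed = 10L))))
})

test_that("the speckle field has unit mean", {
  spk <- gimbalScan:::.withSeed(5L, gimbalScan:::.rrayleighUnit(512 * 512))
  expect_gt(mean(spk), 0.99)
  expect_lt(mean(spk), 1.01)
})

test_that("mean intensity per depth row is non-increasing under attenuation", {
  ph <- buildPhantom(extent = c(40, 40, 30), spacing = 2, textureSeed = 1,
                     textureAmplitude = 0)     # uniform block
  sl <- extractSlice(ph, probePose(20), tinyGeometry(), pixelSpacing = 2)
  img <- renderBMode(sl, imagingParams(attenuation = 0.02, speckle = FALSE))
  expect_true(all(diff(rowMeans(imagePixels(img))) <= 1e-12))
})

test_that("raising lesion contrast never decreases mean intensity inside the mask", {
  geo <- tinyGeometry()
  means <- vapply(c(-0.3, -0.15, 0, 0.2), function(ct) {
    ph <- tinySpherePhantom(contrast = ct, textureAmplitude = 0.05, seed = 4L)
    sl <- extractSlice(ph, probePose(20), geo, pixelSpacing = 2)
    img <- renderBMode(sl, seed = 11L)
    mean(imagePixels(img)[lesionMask(img)])
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("out-of-volume pixels are flagged, background-filled and unlabeled", {
  ph <- tinySpherePhantom()
  geo <- gantryGeometry(railLength = 40, railY = 20, imageWidth = 60,
                        imageDepth = 60)      # plane larger than the phantom
  sl <- extractSlice(ph, probePose(20, pitch = 5), geo, pixelSpacing = 2)
  expect_true(any(sl$outOfVolume))
  expect_true(all(sl$echo[sl$outOfVolume] == ph@background))
  expect_true(all(sl$labels[sl$outOfVolume] == 0L))
  img <- renderBMode(sl, seed = 1L)
  expect_true(validObject(img))
})
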