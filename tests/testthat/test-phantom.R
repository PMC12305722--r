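test_that("phantom grid shape follows extent and spacing", {
  ph <- buildPhantom(extent = c(160, 120, 60), spacing = c(1, 1, 1),
                     textureSeed = 1)
  expect_identical(dim(echoGrid(ph)), c(160L, 120L, 60L))
  expect_identical(dim(lesionLabels(ph)), dim(echoGrid(ph)))

  ph2 <- buildPhantom(extent = c(40, 40, 30), spacing = 2, textureSeed = 1)
  expect_identical(dim(echoGrid(ph2)), c(20L, 20L, 15L))
})

test_that("a lesion-free phantom has zero labels and background-plus-texture echogenicity", {
  ph <- buildPhantom(extent = c(40, 40, 30), spacing = 2, background = 0.35,
                     lesions = list(), textureSeed = 3)
  expect_true(all(lesionLabels(ph) == 0L))
  expect_true(all(abs(echoGrid(ph) - 0.35) < 0.35))   # texture is low amplitude
  expect_gt(stats::sd(echoGrid(ph)), 0)               # but not absent
})

test_that("labeled voxel count matches brute-force sphere enumeration and analytic volume", {
  r <- 6
  ph <- buildPhantom(extent = c(30, 30, 30), spacing = 1,
                     lesions = list(lesionSpec(c(15.5, 15.5, 15.5), r)),
                     textureSeed = 1, textureAmplitude = 0)
  got <- sum(lesionLabels(ph) > 0L)

  # independent oracle: enumerate voxel centers around the lesion
  co <- expand.grid(x = 0:29, y = 0:29, z = 0:29)
  oracle <- sum((co$x - 15.5)^2 + (co$y - 15.5)^2 + (co$z - 15.5)^2 <= r^2)
  expect_identical(got, oracle)
  expect_lt(abs(got - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.02)
})

test_that("every labeled voxel satisfies its lesion's ellipsoid inequality and vice versa", {
  les <- list(lesionSpec(c(10, 12, 8), c(4, 3, 5), -0.2),
              lesionSpec(c(26, 24, 20), 6, 0.3))
  ph <- buildPhantom(extent = c(36, 36, 28), spacing = 2, lesions = les,
                     textureSeed = 2)
  lab <- lesionLabels(ph)
  idx <- which(lab >= 0L, arr.ind = TRUE)          # all voxels
  world <- sweep((idx - 1) * 2, 2, phantomOrigin(ph), "+")
  for (k in seq_along(les)) {
    q <- rowSums(sweep(sweep(world, 2, les[[k]]@center, "-"), 2,
                       les[[k]]@radii, "/")^2)
    expect_identical(as.vector(lab) == k, q <= 1)
  }
})

test_that("phantom generation is bit-identical for a fixed seed", {
  a <- buildPhantom(extent = c(40, 40, 30), spacing = 2,
                    lesions = list(lesionSpec(c(20, 20, 15), 6)),
                    textureSeed = 42)
  b <- buildPhantom(extent = c(40, 40, 30), spacing = 2,
                    lesions = list(lesionSpec(c(20, 20, 15), 6)),
                    textureSeed = 42)
  expect_identical(echoGrid(a), echoGrid(b))
  expect_identical(lesionLabels(a), lesionLabels(b))
  c <- buildPhantom(extent = c(40, 40, 30), spacing = 2,
                    lesions = list(lesionSpec(c(20, 20, 15), 6)),
                    textureSeed = 43)
  expect_false(identical(echoGrid(a), echoGrid(c)))
})

test_that("discretized lesion volume converges to the analytic ellipsoid volume", {
  r <- 6
  vol <- 4 / 3 * pi * r^3
  err <- vapply(c(2, 1, 0.5), function(sp) {
    ph <- buildPhantom(extent = c(20, 20, 20), spacing = sp,
                       lesions = list(lesionSpec(c(10, 10, 10), r)),
                       textureSeed = 1, textureAmplitude = 0)
    abs(sum(lesionLabels(ph) > 0L) * sp^3 - vol)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("invalid lesion placement is rejected with the lesion index", {
  expect_error(
    buildPhantom(extent = c(40, 40, 30), spacing = 2,
                 lesions = list(lesionSpec(c(20, 20, 15), 6),
                                lesionSpec(c(39, 20, 15), 6)),
                 textureSeed = 1),
    "lesion 2")
  expect_error(
    buildPhantom(extent = c(40, 40, 30), spacing = 2,
                 lesions = list(lesionSpec(c(20, 20, 15), 6),
                                lesionSpec(c(22, 20, 15), 6)),
                 textureSeed = 1),
    "overlap")
  expect_error(lesionSpec(c(0, 0, 0), c(5, -1, 5)), "positive")
})

test_that("two-tumor layout places tumor 1 on the scan line and tumor 2 laterally offset", {
  deg <- twoTumorLayout(14, 14, 0)
  expect_length(deg, 2L)
  expect_identical(deg[[1]]@center[2], deg[[2]]@center[2])

  off <- twoTumorLayout(14, 14, 40)
  expect_equal(off[[1]]@center[2], 60)
  expect_equal(off[[2]]@center[2], 100)
  expect_equal(off[[1]]@radii, rep(7, 3))

  mixed <- twoTumorLayout(12, 18, 30)
  expect_equal(mixed[[1]]@radii[1], 6)
  expect_equal(mixed[[2]]@radii[1], 9)

  expect_error(twoTumorLayout(14, 14, 60), "outside the phantom")
  expect_error(twoTumorLayout(10, 14, 40), "within")
})

test_that("NIfTI round trip preserves grids and spacing", {
  ph <- tinySpherePhantom(textureAmplitude = 0.05)
  gf <- tempfile(fileext = ".nii.gz"); lf <- tempfile(fileext = ".nii.gz")
  writePhantom(ph, gf, lf)
  back <- readPhantom(gf, lf)
  expect_equal(echoGrid(back), echoGrid(ph), tolerance = 1e-6)
  expect_identical(lesionLabels(back), lesionLabels(ph))
  expect_equal(voxelSpacing(back), voxelSpacing(ph))
  unlink(c(gf, lf))
})
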