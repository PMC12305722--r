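test_that("the zigzag order matches the stated serpentine rule", {
  # frozen enumeration of the rule for d = 1, sTheta = 1
  expect_identical(unname(zigzagOrder(1, d = 1L)),
                   matrix(c(-1L, -1L, -1L,  0L, 0L,  0L,  1L, 1L, 1L,
                            -1L,  0L,  1L,  1L, 0L, -1L, -1L, 0L, 1L),
                          ncol = 2))
  # d = 0 traverses the primary range in reverse
  expect_identical(unique(zigzagOrder(2, d = 0L)[, "i"]), c(2L, 1L, 0L, -1L, -2L))
  expect_identical(unique(zigzagOrder(2, d = 1L)[, "i"]), c(-2L, -1L, 0L, 1L, 2L))
})

test_that("sweeps visit each lattice pose once, moving one servo one step at a time", {
  for (s in 1:3) for (d in 0:1) {
    ord <- zigzagOrder(s, d)
    expect_identical(nrow(ord), as.integer((2 * s + 1)^2))
    expect_identical(anyDuplicated(ord), 0L)
    moves <- abs(diff(ord))
    expect_true(all(rowSums(moves) == 1L))   # exactly one index changes, by 1
  }
})

test_that("a constant-zero score field leaves the first visited pose as the sweep argmax", {
  fx <- makeFixture("single_centered", seed = 1)
  tr <- angularSweep(40, fx$scan, fx$geometry, fx$phantom,
                     poseScorer(function(p) 0), d = 1L, seed = 1)
  expect_equal(tr@aprob, 0)
  expect_equal(tr@thetaPos, -fx$scan@alpha * fx$scan@sTheta)
  expect_equal(tr@phiPos, -fx$scan@alpha * fx$scan@sTheta)
})

test_that("the station comparison prefers the zero-angle slice on ties", {
  fx <- makeFixture("single_centered", seed = 1)
  # zero-angle scores 0.9, every tilted pose 0.7: linear wins
  st <- stationScan(40, fx$scan, fx$geometry, fx$phantom,
                    poseScorer(function(p)
                      if (p@pitch == 0 && p@roll == 0) 0.9 else 0.7))
  expect_equal(st$lprob, 0.9)
  expect_equal(st$bestScore, 0.9)
  expect_equal(st$bestPose@pitch, 0)

  # a tilted pose scores strictly higher: the sweep argmax wins
  st2 <- stationScan(40, fx$scan, fx$geometry, fx$phantom,
                     poseScorer(function(p)
                       if (p@pitch == 4 && p@roll == 2) 0.95 else 0.5))
  expect_equal(st2$bestScore, 0.95)
  expect_equal(st2$bestPose@pitch, 4)
  expect_equal(st2$bestPose@roll, 2)

  # exact tie between lprob and aprob: zero-angle pose is kept
  st3 <- stationScan(40, fx$scan, fx$geometry, fx$phantom,
                     poseScorer(function(p) 0.6))
  expect_equal(st3$bestPose@pitch, 0)
  expect_equal(st3$bestPose@roll, 0)
})

test_that("a lesion visible only off-axis is found by the sweep, not the zero-angle slice", {
  fx <- makeFixture("off_axis_only", seed = 2)
  st <- stationScan(80, fx$scan, fx$geometry, fx$phantom, fx$scorer,
                    seed = fx$seed, imaging = fx$imaging)
  expect_equal(st$lprob, 0)
  expect_gt(st$bestScore, 0)
  expect_true(st$bestPose@roll != 0)
  # exhaustive per-pose verification of the station argmax
  lat <- rbind(data.frame(x = 80, pitch = 0, roll = 0),
               data.frame(x = 80,
                          pitch = fx$scan@alpha * zigzagOrder(fx$scan@sTheta)[, 1],
                          roll = fx$scan@alpha * zigzagOrder(fx$scan@sTheta)[, 2]))
  bf <- bruteForceSearch(lat, fx$geometry, fx$phantom, fx$scorer,
                         seed = fx$seed, pixelSpacing = fx$scan@pixelSpacing,
                         imaging = fx$imaging)
  expect_equal(st$bestScore, bf$bestScore)
  expect_equal(st$bestPose@roll, bf$bestPose@roll)
})

test_that("refinement halves the step each round down to epsilon and never worsens", {
  fx <- makeFixture("single_centered", seed = 3)
  res <- optimalSliceSearch(fx$scan, fx$geometry, fx$phantom, fx$scorer,
                            seed = fx$seed, imaging = fx$imaging)
  rd <- roundSummary(res)
  expect_equal(rd$step, c(32, 16, 8, 4, 2, 1))
  expect_true(all(diff(rd$bestScore) >= 0))
  # conservation: stations x (1 + sweep size) poses per round
  sweepSize <- (2L * fx$scan@sTheta + 1L)^2
  expect_identical(nrow(evaluations(res)),
                   as.integer(sum(rd$nStations * (1L + sweepSize))))
  # cheaper than exhaustive search on the epsilon-resolution lattice
  span <- (fx$scan@nstep - 1) * fx$scan@slin0
  bruteCount <- (span / fx$scan@epsilon + 1) * (1 + sweepSize)
  expect_lt(nrow(evaluations(res)), bruteCount)
})

test_that("a constant-zero score field returns the first evaluated pose", {
  fx <- makeFixture("single_centered", seed = 1)
  res <- optimalSliceSearch(fx$scan, fx$geometry, fx$phantom,
                            poseScorer(function(p) 0), seed = 1)
  expect_equal(bestScore(res), 0)
  expect_equal(bestPose(res)@x, fx$scan@xStart)
  expect_equal(bestPose(res)@pitch, 0)
  expect_equal(bestPose(res)@roll, 0)
})

test_that("memoized revisits return identical scores", {
  fx <- makeFixture("single_centered", seed = 4)
  ev <- evaluations(optimalSliceSearch(fx$scan, fx$geometry, fx$phantom,
                                       fx$scorer, seed = fx$seed,
                                       imaging = fx$imaging))
  key <- sprintf("%.6f|%.4f|%.4f", ev$x, ev$pitch, ev$roll)
  expect_gt(sum(duplicated(key)), 0)   # refinement does revisit poses
  byKey <- tapply(ev$probability, key, function(v) length(unique(v)))
  expect_true(all(byKey == 1L))
})

test_that("the search is bit-deterministic for a fixed seed", {
  fx <- makeFixture("single_centered", seed = 5)
  a <- optimalSliceSearch(fx$scan, fx$geometry, fx$phantom, fx$scorer,
                          seed = 5, imaging = fx$imaging)
  b <- optimalSliceSearch(fx$scan, fx$geometry, fx$phantom, fx$scorer,
                          seed = 5, imaging = fx$imaging)
  expect_identical(evaluations(a), evaluations(b))
  expect_identical(bestScore(a), bestScore(b))
  expect_identical(bestPose(a)@x, bestPose(b)@x)
})

test_that("brute force enumerates exactly and agrees with its own score list", {
  fx <- makeFixture("single_centered", seed = 6)
  one <- data.frame(x = 80, pitch = 0, roll = 0)
  bf1 <- bruteForceSearch(one, fx$geometry, fx$phantom, fx$scorer, seed = 6,
                          pixelSpacing = 2, imaging = fx$imaging)
  expect_equal(bf1$bestPose@x, 80)
  expect_identical(bf1$bestScore, bf1$scores[1])

  lat <- data.frame(x = seq(60, 100, by = 4), pitch = 0, roll = 0)
  bf <- bruteForceSearch(lat, fx$geometry, fx$phantom, fx$scorer, seed = 6,
                         pixelSpacing = 2, imaging = fx$imaging)
  expect_identical(bf$bestScore, max(bf$scores))
})

test_that("invalid configurations are rejected before any scanning", {
  expect_error(scanConfig(slin0 = 1, epsilon = 2), "slin0 > epsilon")
  expect_error(scanConfig(sTheta = 5L, alpha = 2, thetaMax = 4, phiMax = 20),
               "thetaMax")
  expect_error(scanConfig(refineFactor = 1), "refineFactor")
  fx <- makeFixture("single_centered", seed = 1)
  bad <- scanConfig(xStart = 150, slin0 = 32, nstep = 5L, epsilon = 1,
                    thetaMax = 4, phiMax = 4)
  expect_error(optimalSliceSearch(bad, fx$geometry, fx$phantom, fx$scorer),
               "rail")
})
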