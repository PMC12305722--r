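#' Construct a scan-search configuration
#'
#' @param xStart rail position of the first station (mm).
#' @param slin0 initial linear step (mm).
#' @param nstep stations in the first round.
#' @param sTheta angular index half-range (the sweep covers indices
#'   -sTheta..sTheta on both gimbal axes).
#' @param alpha degrees per angular index; the gantry's fixed angular
#'   resolution, 2 degrees by default.
#' @param epsilon refinement stop threshold (mm); rounds continue while the
#'   linear step is at least epsilon.
#' @param thetaMax,phiMax pitch/roll bounds (degrees); \code{alpha * sTheta}
#'   may not exceed either.
#' @param refineFactor step divisor per refinement round (> 1).
#' @param tau detection threshold on probability, in (0, 1).
#' @param pixelSpacing mm per pixel for slices rendered during the search.
#' @return A \linkS4class{ScanConfig}.
#' @examples
#' scanConfig(slin0 = 32, nstep = 5, epsilon = 1)
#' @export
scanConfig <- function(xStart = 0, slin0 = 32, nstep = 5L, sTheta = 2L,
                       alpha = 2, epsilon = 1, thetaMax = alpha * sTheta,
                       phiMax = alpha * sTheta, refineFactor = 2, tau = 0.5,
                       pixelSpacing = 2) {
  new("ScanConfig", xStart = as.numeric(xStart), slin0 = as.numeric(slin0),
      nstep = as.integer(nstep), sTheta = as.integer(sTheta),
      alpha = as.numeric(alpha), epsilon = as.numeric(epsilon),
      thetaMax = as.numeric(thetaMax), phiMax = as.numeric(phiMax),
      refineFactor = as.numeric(refineFactor), tau = as.numeric(tau),
      pixelSpacing = as.numeric(pixelSpacing))
}

#' Zigzag traversal order of the angular index grid
#'
#' The primary (pitch) range P is -sTheta..sTheta when the direction
#' indicator d is 1 and reversed when d is 0.  For the r-th value of P
#' (r = 0, 1, ...), the secondary (roll) range runs forward when r is even
#' and backward when r is odd — a serpentine path on which every move is a
#' single step of a single servo.
#'
#' @param sTheta index half-range, >= 0.
#' @param d direction indicator, 0 or 1.
#' @return Integer matrix with columns \code{i} (pitch index) and \code{j}
#'   (roll index), one row per visited pose, \code{(2 sTheta + 1)^2} rows.
#' @examples
#' zigzagOrder(1, d = 1)
#' @export
zigzagOrder <- function(sTheta, d = 1L) {
  stopifnot(sTheta >= 0, d %in% c(0L, 1L))
  s <- as.integer(sTheta)
  P <- if (d == 1L) seq.int(-s, s) else seq.int(s, -s)
  fwd <- seq.int(-s, s)
  rows <- lapply(seq_along(P), function(r) {
    Rr <- if ((r - 1L) %% 2L == 0L) fwd else rev(fwd)
    cbind(i = rep.int(P[r], length(Rr)), j = Rr)
  })
  do.call(rbind, rows)
}

# Evaluation context shared by the search routines: memoizes per-pose scores
# on the actuator lattice and logs every evaluation in visit order.
.newScanContext <- function(phantom, geometry, config, scorer, seed, imaging) {
  ctx <- new.env(parent = emptyenv())
  ctx$cache <- new.env(hash = TRUE, parent = emptyenv())
  ctx$rows <- list()
  ctx$areas <- list()
  ctx$n <- 0L
  nLesions <- length(phantom@lesions)
  ctx$evaluate <- function(x, pitch, roll, round, station) {
    key <- sprintf("%.6f|%.4f|%.4f", x, pitch, roll)
    hit <- ctx$cache[[key]]
    if (is.null(hit)) {
      img <- acquireBMode(phantom, probePose(x, pitch = pitch, roll = roll),
                          geometry, pixelSpacing = config@pixelSpacing,
                          imaging = imaging, seed = seed)
      hit <- list(prob = scorer(img),
                  areas = .lesionAreaFractions(img, nLesions))
      ctx$cache[[key]] <- hit
    }
    n <- ctx$n + 1L
    ctx$n <- n
    ctx$rows[[n]] <- data.frame(order = n, round = round, station = station,
                                x = x, pitch = pitch, roll = roll,
                                probability = hit$prob)
    ctx$areas[[n]] <- hit$areas
    hit$prob
  }
  ctx
}

.ctxEvaluations <- function(ctx) {
  if (!ctx$n) return(data.frame(order = integer(), round = integer(),
                                station = integer(), x = numeric(),
                                pitch = numeric(), roll = numeric(),
                                probability = numeric()))
  do.call(rbind, ctx$rows)
}

#' Zigzag angular sweep at one station
#'
#' Visits every pose \code{(x, pitch = alpha * i, roll = alpha * j)} for
#' indices i, j in -sTheta..sTheta in the serpentine order of
#' \code{\link{zigzagOrder}}, scoring each rendered slice.  Ties for the
#' best score go to the first-visited pose.
#'
#' @param x station rail position (mm).
#' @param config a \linkS4class{ScanConfig}.
#' @param geometry a \linkS4class{GantryGeometry}.
#' @param phantom a \linkS4class{Phantom}.
#' @param scorer function(\linkS4class{BModeImage}) -> probability.
#' @param d direction indicator, 0 or 1.
#' @param seed global integer seed (drives per-pose speckle).
#' @param imaging an \code{\link{imagingParams}} list.
#' @return A \linkS4class{SweepTrace}.
#' @export
angularSweep <- function(x, config, geometry, phantom,
                         scorer = analyticScorer(), d = 1L, seed = 0L,
                         imaging = imagingParams()) {
  validObject(config)
  ctx <- .newScanContext(phantom, geometry, config, scorer, seed, imaging)
  .sweep(x, config, d, ctx, round = 1L, station = 0L)
}

.sweep <- function(x, config, d, ctx, round, station) {
  ord <- zigzagOrder(config@sTheta, d)
  scores <- vapply(seq_len(nrow(ord)), function(r) {
    ctx$evaluate(x, config@alpha * ord[r, 1L], config@alpha * ord[r, 2L],
                 round, station)
  }, numeric(1))
  best <- which.max(scores)  # first maximum on ties
  new("SweepTrace", d = as.integer(d), visited = ord, scores = scores,
      aprob = scores[best],
      thetaPos = config@alpha * as.numeric(ord[best, 1L]),
      phiPos = config@alpha * as.numeric(ord[best, 2L]))
}

#' Scan one station: zero-angle score plus angular sweep
#'
#' Scores the straight-down slice at the station (\code{lprob}), then runs
#' the zigzag sweep with direction indicator \code{d = k mod 2} (alternating
#' with the station index k).  The station's best pose is the zero-angle
#' pose when \code{lprob >= aprob} (linear preferred on exact ties) and the
#' sweep's argmax orientation otherwise.
#'
#' @inheritParams angularSweep
#' @param stationIndex 0-based station index k; sets \code{d = k mod 2}.
#' @return List with \code{lprob}, \code{trace} (a
#'   \linkS4class{SweepTrace}), \code{bestPose} and \code{bestScore}.
#' @export
stationScan <- function(x, config, geometry, phantom,
                        scorer = analyticScorer(), stationIndex = 0L,
                        seed = 0L, imaging = imagingParams()) {
  validObject(config)
  ctx <- .newScanContext(phantom, geometry, config, scorer, seed, imaging)
  .stationScan(x, config, ctx, stationIndex, round = 1L)
}

.stationScan <- function(x, config, ctx, stationIndex, round) {
  d <- as.integer(stationIndex) %% 2L
  lprob <- ctx$evaluate(x, 0, 0, round, stationIndex)
  trace <- .sweep(x, config, d, ctx, round, stationIndex)
  if (lprob >= trace@aprob)
    list(lprob = lprob, trace = trace, bestPose = probePose(x),
         bestScore = lprob)
  else
    list(lprob = lprob, trace = trace,
         bestPose = probePose(x, pitch = trace@thetaPos, roll = trace@phiPos),
         bestScore = trace@aprob)
}

#' Two-level optimal-slice search
#'
#' The package's core procedure.  Round 1 scans \code{nstep} stations spaced
#' \code{slin0} mm apart, each station scoring its zero-angle slice and (in
#' angular mode) running the zigzag sweep.  Every later round divides the
#' step by \code{refineFactor} and re-scans a window of half-width equal to
#' the previous step centered on the incumbent best rail position; rounds
#' continue while the step is at least \code{epsilon}.  The incumbent best
#' is updated by strict improvement, so ties go to the first-visited pose and
#' (at a station) to the zero-angle slice.  Revisited poses are memoized on
#' the actuator lattice and return identical scores.
#'
#' @inheritParams angularSweep
#' @param mode \code{"angular"} (full sweeps) or \code{"linear"} (zero-angle
#'   slices only, emulating a gantry without the gimbal).
#' @return A \linkS4class{ScanResult}.
#' @examples
#' fx <- makeFixture("single_centered", seed = 1)
#' res <- optimalSliceSearch(fx$scan, fx$geometry, fx$phantom, seed = 1)
#' bestPose(res); bestScore(res)
#' @export
optimalSliceSearch <- function(config, geometry, phantom,
                               scorer = analyticScorer(), seed = 0L,
                               mode = c("angular", "linear"),
                               imaging = imagingParams()) {
  mode <- match.arg(mode)
  validObject(config); validObject(geometry); validObject(phantom)
  stations0 <- enumerateStations(config@xStart, config@slin0, config@nstep,
                                 geometry)
  ctx <- .newScanContext(phantom, geometry, config, scorer, seed, imaging)
  bestScore <- -Inf
  bestPose <- NULL
  rounds <- list()
  statRows <- list()

  runRound <- function(stations, roundIdx, step) {
    firstEval <- ctx$n + 1L
    for (k in seq_along(stations)) {
      x <- stations[k]
      si <- k - 1L
      if (mode == "linear") {
        lprob <- ctx$evaluate(x, 0, 0, roundIdx, si)
        statRows[[length(statRows) + 1L]] <<- data.frame(
          round = roundIdx, station = si, x = x, lprob = lprob, aprob = NA_real_)
      } else {
        st <- .stationScan(x, config, ctx, si, roundIdx)
        statRows[[length(statRows) + 1L]] <<- data.frame(
          round = roundIdx, station = si, x = x, lprob = st$lprob,
          aprob = st$trace@aprob)
      }
    }
    # strict-improvement scan over this round's evaluations, in visit order
    for (n in firstEval:ctx$n) {
      row <- ctx$rows[[n]]
      if (row$probability > bestScore) {
        bestScore <<- row$probability
        bestPose <<- probePose(row$x, pitch = row$pitch, roll = row$roll)
      }
    }
    rounds[[length(rounds) + 1L]] <<- data.frame(
      round = roundIdx, step = step, nStations = length(stations),
      bestScore = bestScore)
  }

  step <- config@slin0
  roundIdx <- 1L
  runRound(stations0, roundIdx, step)
  repeat {
    nextStep <- step / config@refineFactor
    if (nextStep < config@epsilon - 1e-12) break
    window <- .seqStep(bestPose@x - step, bestPose@x + step, nextStep)
    window <- window[window >= -1e-9 & window <= geometry@railLength + 1e-9]
    window <- unique(round(pmin(pmax(window, 0), geometry@railLength), 9))
    step <- nextStep
    roundIdx <- roundIdx + 1L
    runRound(window, roundIdx, step)
  }

  new("ScanResult", mode = mode, evaluations = .ctxEvaluations(ctx),
      lesionAreas = do.call(rbind, ctx$areas),
      rounds = do.call(rbind, rounds), stationScores = do.call(rbind, statRows),
      Lmax = bestPose, Pmax = bestScore)
}

#' First-visit deduplicated pose lattice of a scan
#'
#' The unique poses a search evaluated, in first-visit order — the lattice
#' over which \code{\link{bruteForceSearch}} provides the exhaustive oracle.
#'
#' @param result a \linkS4class{ScanResult}.
#' @return data.frame with columns x, pitch, roll.
#' @export
visitedLattice <- function(result) {
  ev <- evaluations(result)
  key <- sprintf("%.6f|%.4f|%.4f", ev$x, ev$pitch, ev$roll)
  ev[!duplicated(key), c("x", "pitch", "roll")]
}

#' Exhaustive search over a pose lattice
#'
#' Validation oracle: scores every pose of a finite lattice by full
#' enumeration and returns the exact maximum, breaking ties by first visit.
#' Images are acquired with the same per-pose seeding as the scan search, so
#' a pose scores identically here and there.
#'
#' @param poses data.frame with columns x, pitch, roll (visit order = row
#'   order).
#' @param geometry a \linkS4class{GantryGeometry}.
#' @param phantom a \linkS4class{Phantom}.
#' @param scorer function(image) -> probability.
#' @param seed global integer seed.
#' @param pixelSpacing mm per pixel for the rendered slices.
#' @param imaging an \code{\link{imagingParams}} list.
#' @return List with \code{bestPose} (\linkS4class{ProbePose}),
#'   \code{bestScore}, and \code{scores} for all poses in row order.
#' @export
bruteForceSearch <- function(poses, geometry, phantom,
                             scorer = analyticScorer(), seed = 0L,
                             pixelSpacing = 2, imaging = imagingParams()) {
  stopifnot(is.data.frame(poses), nrow(poses) >= 1L,
            all(c("x", "pitch", "roll") %in% names(poses)))
  scores <- numeric(nrow(poses))
  bestScore <- -Inf
  bestRow <- 1L
  for (r in seq_len(nrow(poses))) {
    img <- acquireBMode(phantom,
                        probePose(poses$x[r], pitch = poses$pitch[r],
                                  roll = poses$roll[r]),
                        geometry, pixelSpacing = pixelSpacing,
                        imaging = imaging, seed = seed)
    scores[r] <- scorer(img)
    if (scores[r] > bestScore) {
      bestScore <- scores[r]
      bestRow <- r
    }
  }
  list(bestPose = probePose(poses$x[bestRow], pitch = poses$pitch[bestRow],
                            roll = poses$roll[bestRow]),
       bestScore = bestScore, scores = scores)
}

#' Compare linear-only and angular scanning on the same phantom
#'
#' Runs the search once with the gimbal disabled (zero-angle slices only, a
#' plain linear gantry) and once with the full angular sweep, then
#' attributes detections per lesion: a lesion's probability under a mode is
#' the analytic probability of the largest in-volume area fraction it
#' reached in any slice of that mode, \code{a / (a + halfSat)} — exactly 0
#' for a lesion no slice ever imaged.  A lesion is flagged undetected when
#' its probability falls below \code{tau}.
#'
#' @inheritParams optimalSliceSearch
#' @param halfSat half-saturation area fraction of the analytic attribution.
#' @param tau detection threshold; defaults to the config's.
#' @return List with \code{linear} and \code{angular}
#'   (\linkS4class{ScanResult}s) and \code{table}, a data.frame with one row
#'   per lesion x mode: maxArea, probability, detected.
#' @export
compareLinearAngular <- function(config, geometry, phantom,
                                 scorer = analyticScorer(), seed = 0L,
                                 imaging = imagingParams(), halfSat = 0.02,
                                 tau = NULL) {
  if (is.null(tau)) tau <- config@tau
  lin <- optimalSliceSearch(config, geometry, phantom, scorer, seed,
                            mode = "linear", imaging = imaging)
  ang <- optimalSliceSearch(config, geometry, phantom, scorer, seed,
                            mode = "angular", imaging = imaging)
  nL <- length(phantom@lesions)
  tab <- rbind(.lesionDetectionTable(lin, nL, halfSat, tau),
               .lesionDetectionTable(ang, nL, halfSat, tau))
  list(linear = lin, angular = ang, table = tab)
}

# Per-lesion detection attribution for one scan result: probability of the
# largest in-volume area fraction the lesion reached in any slice.
.lesionDetectionTable <- function(res, nLesions, halfSat, tau) {
  maxA <- if (nLesions) apply(lesionAreaFractions(res), 2L, max) else numeric()
  p <- ifelse(maxA > 0, maxA / (maxA + halfSat), 0)
  data.frame(lesion = seq_len(nLesions), mode = res@mode, maxArea = maxA,
             probability = p, detected = p >= tau)
}
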