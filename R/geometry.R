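#' Construct the gantry geometry
#'
#' Defaults follow the physical build: a NEMA-17 stepper (1.8 degree step
#' angle, 200 steps per revolution) driving a TR8x2 trapezoidal screw with
#' 2 mm lead, giving a 0.01 mm linear quantum, and two positioning servos
#' with 1 degree resolution.  Imaging-plane extent defaults to 60 x 60 mm.
#'
#' @param railLength usable rail travel (mm).
#' @param railY lateral world coordinate of the rail / central scan line (mm).
#' @param pivotHeight gimbal pivot height above the phantom surface (mm).
#' @param imageWidth,imageDepth imaging-plane extent (mm).
#' @param sliceThickness elevation slab thickness (mm), used for coverage.
#' @param stepsPerRev stepper full steps per revolution.
#' @param screwLead screw travel per revolution (mm).
#' @param servoResolution servo angular quantum (degrees).
#' @return A \linkS4class{GantryGeometry}.
#' @examples
#' gantryGeometry()
#' @export
gantryGeometry <- function(railLength = 160, railY = 60, pivotHeight = 10,
                           imageWidth = 60, imageDepth = 60,
                           sliceThickness = 2, stepsPerRev = 200L,
                           screwLead = 2, servoResolution = 1) {
  new("GantryGeometry", railLength = as.numeric(railLength),
      railY = as.numeric(railY), pivotHeight = as.numeric(pivotHeight),
      imageWidth = as.numeric(imageWidth), imageDepth = as.numeric(imageDepth),
      sliceThickness = as.numeric(sliceThickness),
      stepsPerRev = as.integer(stepsPerRev), screwLead = as.numeric(screwLead),
      servoResolution = as.numeric(servoResolution))
}

#' Construct a probe pose
#'
#' @param x rail position (mm).
#' @param pitch,roll gimbal angles (degrees).
#' @param y lateral offset (mm); the gantry has a single actuated linear
#'   axis, so y is 0 throughout this package.
#' @return A \linkS4class{ProbePose}.
#' @examples
#' probePose(50, pitch = 4, roll = -2)
#' @export
probePose <- function(x, pitch = 0, roll = 0, y = 0) {
  new("ProbePose", x = as.numeric(x), y = as.numeric(y),
      pitch = as.numeric(pitch), roll = as.numeric(roll))
}

# Rotation matrices about world axes (degrees)
.rotY <- function(deg) {
  t <- deg * pi / 180; c <- cos(t); s <- sin(t)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}
.rotX <- function(deg) {
  t <- deg * pi / 180; c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}

#' Map a probe pose to its oriented imaging plane
#'
#' The gimbal pivot sits \code{pivotHeight} mm above the phantom surface, on
#' the rail at the pose's x.  Pitch rotates the probe about the lateral
#' (world y) axis through the pivot, then roll rotates it about the travel
#' (world x) axis — a fixed, documented composition order, since a gimbal
#' composition is inherently order-dependent.  At pitch = roll = 0 the plane
#' normal is the rail axis +x and the plane is the lateral--depth plane at
#' the pose's x.
#'
#' @param pose a \linkS4class{ProbePose}.
#' @param geometry a \linkS4class{GantryGeometry}.
#' @return List with \code{origin} (the probe contact point, mm), orthonormal
#'   in-plane basis \code{u} (lateral) and \code{v} (depth), and unit normal
#'   \code{n}.
#' @examples
#' pl <- poseToPlane(probePose(50), gantryGeometry())
#' pl$n          # c(1, 0, 0)
#' @export
poseToPlane <- function(pose, geometry) {
  stopifnot(is(pose, "ProbePose"), is(geometry, "GantryGeometry"))
  R <- .rotX(pose@roll) %*% .rotY(pose@pitch)
  pivot <- c(pose@x, geometry@railY + pose@y, -geometry@pivotHeight)
  list(origin = as.numeric(pivot + R %*% c(0, 0, geometry@pivotHeight)),
       u = as.numeric(R[, 2]),
       v = as.numeric(R[, 3]),
       n = as.numeric(R[, 1]))
}

#' Motor commands to move between two poses
#'
#' Emulates the open-loop command stream of the gantry: the stepper is
#' commanded by a whole number of steps (rounding |dx| to the nearest step of
#' \code{screwLead / stepsPerRev} mm, 0.01 mm with the defaults), and each
#' servo whose target changed receives one absolute-angle command.
#'
#' @param from,to \linkS4class{ProbePose} endpoints.
#' @param geometry a \linkS4class{GantryGeometry}.
#' @return A data.frame with columns \code{kind} ("stepper", "servo1",
#'   "servo2"), \code{magnitude} (steps, or target degrees) and
#'   \code{direction} (+1/-1 for the stepper, NA for servos); zero rows when
#'   the poses coincide.
#' @examples
#' poseToMotorCommands(probePose(0), probePose(2), gantryGeometry())  # 200 steps
#' @export
poseToMotorCommands <- function(from, to, geometry) {
  stopifnot(is(from, "ProbePose"), is(to, "ProbePose"),
            is(geometry, "GantryGeometry"))
  cmds <- list()
  dx <- to@x - from@x
  steps <- round(abs(dx) / geometry@screwLead * geometry@stepsPerRev)
  if (steps > 0)
    cmds[[length(cmds) + 1L]] <- data.frame(
      kind = "stepper", magnitude = steps, direction = sign(dx))
  if (to@pitch != from@pitch)
    cmds[[length(cmds) + 1L]] <- data.frame(
      kind = "servo1", magnitude = to@pitch, direction = NA_real_)
  if (to@roll != from@roll)
    cmds[[length(cmds) + 1L]] <- data.frame(
      kind = "servo2", magnitude = to@roll, direction = NA_real_)
  if (!length(cmds))
    return(data.frame(kind = character(), magnitude = numeric(),
                      direction = numeric()))
  do.call(rbind, cmds)
}

#' Apply a motor-command stream to a pose
#'
#' Open-loop actuator emulation: stepper steps advance x by exact multiples
#' of the step quantum; servo commands snap the target angle to the servo
#' resolution.  Feeding the output of \code{\link{poseToMotorCommands}} back
#' through this function reproduces the target pose within one stepper step
#' and one servo quantum.
#'
#' @param pose starting \linkS4class{ProbePose}.
#' @param commands data.frame as returned by \code{\link{poseToMotorCommands}}.
#' @param geometry a \linkS4class{GantryGeometry}.
#' @return The resulting \linkS4class{ProbePose}.
#' @export
applyMotorCommands <- function(pose, commands, geometry) {
  stopifnot(is(pose, "ProbePose"), is(geometry, "GantryGeometry"))
  x <- pose@x; pitch <- pose@pitch; roll <- pose@roll
  res <- geometry@servoResolution
  for (r in seq_len(nrow(commands))) {
    kind <- commands$kind[r]
    mag <- commands$magnitude[r]
    if (kind == "stepper") {
      x <- x + commands$direction[r] * mag * geometry@screwLead / geometry@stepsPerRev
    } else if (kind == "servo1") {
      pitch <- round(mag / res) * res
    } else if (kind == "servo2") {
      roll <- round(mag / res) * res
    } else stop("unknown motor command kind: ", kind)
  }
  probePose(x, pitch = pitch, roll = roll, y = pose@y)
}

#' Write a motor-command stream as a plain-text log
#'
#' One command per line: \code{STEP <n> <dir>}, \code{SERVO1 <deg>},
#' \code{SERVO2 <deg>} — bit-exact and diffable.
#'
#' @param commands data.frame from \code{\link{poseToMotorCommands}}.
#' @param file output path or connection.
#' @return The lines, invisibly.
#' @export
writeCommandLog <- function(commands, file) {
  lines <- vapply(seq_len(nrow(commands)), function(r) {
    if (commands$kind[r] == "stepper")
      sprintf("STEP %d %+d", as.integer(commands$magnitude[r]),
              as.integer(commands$direction[r]))
    else
      sprintf("%s %.6g", toupper(commands$kind[r]), commands$magnitude[r])
  }, character(1))
  writeLines(lines, file)
  invisible(lines)
}

#' Enumerate linear scan stations
#'
#' Arithmetic progression of rail positions \code{xStart + k * slin},
#' k = 0..nstep-1.  A station beyond the rail is a configuration error.
#'
#' @param xStart first station (mm).
#' @param slin linear step (mm), positive.
#' @param nstep number of stations.
#' @param geometry a \linkS4class{GantryGeometry} providing the rail bound.
#' @return Numeric vector of station positions.
#' @examples
#' enumerateStations(0, 10, 5, gantryGeometry())  # 0 10 20 30 40
#' @export
enumerateStations <- function(xStart, slin, nstep, geometry) {
  stopifnot(slin > 0, nstep >= 1, xStart >= 0)
  x <- xStart + slin * (seq_len(nstep) - 1)
  if (any(x > geometry@railLength + 1e-9))
    stop(sprintf("station at %.3f mm exceeds the rail length (%.3f mm)",
                 max(x), geometry@railLength))
  x
}
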