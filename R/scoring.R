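#' Analytic tumor-presence score
#'
#' Deterministic surrogate for a trained slice classifier: the probability of
#' tumor presence is a saturating monotone function of the lesion area
#' fraction of the slice, \code{p = a / (a + halfSat)}, where \code{a} is the
#' fraction of in-volume pixels carrying a lesion label.  \code{p(0) = 0} and
#' \code{p = 0.5} exactly when the lesion occupies \code{halfSat} of the
#' slice.  The returned saliency is the ground-truth lesion mask — the ideal
#' class-activation map for this scorer.
#'
#' @param image a \linkS4class{BModeImage}.
#' @param halfSat half-saturation area fraction (default 0.02: a slice 2
#'   percent occupied by lesion scores 0.5).
#' @return A \linkS4class{SliceScore}.
#' @examples
#' ph <- buildPhantom(extent = c(40, 40, 30), spacing = 2,
#'                    lesions = list(lesionSpec(c(20, 20, 15), 6)),
#'                    textureSeed = 1)
#' geo <- gantryGeometry(railLength = 40, railY = 20, imageWidth = 30,
#'                       imageDepth = 30)
#' probability(analyticScore(acquireBMode(ph, probePose(20), geo, 2, seed = 1)))
#' @export
analyticScore <- function(image, halfSat = 0.02) {
  stopifnot(is(image, "BModeImage"), halfSat > 0)
  nIn <- sum(!image@outOfVolume)
  if (nIn == 0L) {
    warning("all pixels fall outside the phantom; probability is 0")
    return(new("SliceScore", probability = 0,
               saliency = matrix(0, nrow(image@pixels), ncol(image@pixels))))
  }
  a <- sum(image@labels > 0L) / nIn
  new("SliceScore", probability = a / (a + halfSat),
      saliency = (image@labels > 0L) * 1)
}

#' Analytic scorer as a black-box score function
#'
#' @param halfSat half-saturation area fraction.
#' @return A function mapping a \linkS4class{BModeImage} to a probability in
#'   [0, 1], suitable as the \code{scorer} of the search functions and the
#'   black box of \code{\link{occlusionSaliency}}.
#' @export
analyticScorer <- function(halfSat = 0.02) {
  force(halfSat)
  function(image) suppressWarnings(probability(analyticScore(image, halfSat)))
}

# Per-lesion in-volume area fractions of a slice (for detection attribution)
.lesionAreaFractions <- function(image, nLesions) {
  nIn <- sum(!image@outOfVolume)
  if (nIn == 0L || nLesions == 0L) return(rep(0, nLesions))
  counts <- tabulate(image@labels[image@labels > 0L], nbins = nLesions)
  counts / nIn
}

#' Occlusion saliency for a black-box scorer
#'
#' Model-agnostic stand-in for a gradient class-activation map: slide a
#' square patch over the image, replace its content (pixels and lesion
#' labels) by background, and record how much the score drops.  Each pixel
#' accumulates \code{max(0, score(image) - score(occluded))} over every patch
#' covering it; the accumulated map is normalized to [0, 1] (all zeros when
#' no occlusion reduces the score, e.g. for a constant scorer).
#'
#' @param image a \linkS4class{BModeImage}.
#' @param scorer function(image) -> probability.
#' @param patch patch side (pixels), >= 1 and no larger than the image.
#' @param stride grid stride (pixels), >= 1.
#' @param background replacement intensity; default: median intensity of the
#'   non-lesion pixels.
#' @return A saliency matrix in [0, 1], same shape as the image.
#' @export
occlusionSaliency <- function(image, scorer, patch = 5L, stride = 2L,
                              background = NULL) {
  stopifnot(is(image, "BModeImage"), patch >= 1, stride >= 1)
  d <- dim(image@pixels)
  if (patch > min(d)) stop("'patch' is larger than the image")
  if (is.null(background)) {
    bg <- image@pixels[image@labels == 0L]
    background <- if (length(bg)) stats::median(bg) else 0
  }
  baseScore <- scorer(image)
  starts <- function(n) unique(c(seq(1L, n - patch + 1L, by = stride),
                                 n - patch + 1L))
  sal <- matrix(0, d[1], d[2])
  for (r0 in starts(d[1])) {
    rows <- r0:(r0 + patch - 1L)
    for (c0 in starts(d[2])) {
      cols <- c0:(c0 + patch - 1L)
      occ <- image
      occ@pixels[rows, cols] <- background
      occ@labels[rows, cols] <- 0L
      drop <- max(0, baseScore - scorer(occ))
      if (drop > 0) sal[rows, cols] <- sal[rows, cols] + drop
    }
  }
  m <- max(sal)
  if (m > 0) sal <- sal / m
  sal
}

#' Threshold a saliency map into a predicted tumor mask
#'
#' Pixels at or above \code{t} times the maximum saliency are kept and the
#' largest connected component (8-connectivity) is returned, mirroring the
#' usual segmentation of a class-activation heatmap.  An all-zero saliency
#' yields an empty mask.
#'
#' @param saliency non-negative matrix.
#' @param t threshold fraction in (0, 1).
#' @return Logical matrix.
#' @export
saliencyToMask <- function(saliency, t = 0.5) {
  stopifnot(is.matrix(saliency), t > 0, t < 1)
  m <- max(saliency)
  if (m <= 0) return(matrix(FALSE, nrow(saliency), ncol(saliency)))
  bin <- saliency >= t * m
  lab <- EBImage::bwlabel(bin)
  n <- max(lab)
  if (n <= 1) return(bin)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  lab == which.max(sizes)
}

#' Dice coefficient and intersection-over-union of two masks
#'
#' \code{dice = 2|A&B| / (|A| + |B|)}, \code{iou = |A&B| / |A|B|}; both are
#' defined as 1 when both masks are empty (correct prediction of absence).
#'
#' @param maskA,maskB logical (or 0/1) matrices of identical shape.
#' @return Named numeric vector \code{c(dice = ..., iou = ...)}.
#' @examples
#' a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
#' diceIou(a, a)   # 1, 1
#' @export
diceIou <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)))
    stop("masks must have identical shape")
  a <- as.logical(maskA); b <- as.logical(maskB)
  inter <- sum(a & b)
  union <- sum(a | b)
  sizes <- sum(a) + sum(b)
  if (union == 0L) return(c(dice = 1, iou = 1))
  c(dice = 2 * inter / sizes, iou = inter / union)
}
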