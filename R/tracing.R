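# Axon detection inside a region of interest: crop, tissue-hole repair,
# ridge filtering with second-order Gaussian-scaled derivatives in x and y,
# sensitivity thresholding, skeletonization, particle cleanup, measurement.

#' Apply a ROI to a plane and crop to its bounding box
#'
#' Pixels outside the region are set to zero and the plane is cropped to the
#' tight bounding box of the region, which shrinks every later step's working
#' frame. The 1-based (row, col) origin of the crop in the source frame is
#' returned alongside.
#'
#' @param plane numeric H x W matrix.
#' @param roi a [RoiMask-class] with at least one pixel.
#' @return list with \code{plane} (cropped, masked), \code{mask} (cropped
#'   logical), \code{offset} (integer row, col).
#' @export
applyRoiAndCrop <- function(plane, roi) {
  stopifnot(is(roi, "RoiMask"))
  if (!identical(dim(plane), dim(roi@mask)))
    stop("plane and ROI dimensions differ")
  if (!any(roi@mask)) stop("empty ROI")
  rows <- range(which(rowSums(roi@mask) > 0))
  cols <- range(which(colSums(roi@mask) > 0))
  m <- roi@mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  p <- plane[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  p[!m] <- 0
  list(plane = p, mask = m, offset = c(rows[1], cols[1]))
}

#' Detect tissue holes
#'
#' Holes are connected near-black regions -- intensity at most
#' \code{p@holeIntensityMax} and area at least \code{p@holeMinAreaPx}. Their
#' sharp edges would otherwise be detected as (false) axons. If every pixel
#' of the plane qualifies there is no tissue at all and a degenerate-image
#' error is raised.
#'
#' @param plane numeric H x W matrix on the 0-255 scale.
#' @param p a [DetectionParams-class].
#' @return logical hole mask.
#' @export
detectTissueHoles <- function(plane, p = detectionParams()) {
  cand <- plane <= p@holeIntensityMax
  if (all(cand)) stop("degenerate image: every pixel qualifies as a hole")
  if (!any(cand)) return(cand)
  filterComponents(cand, function(sz) sz >= p@holeMinAreaPx)
}

#' Fill holes with the mean tissue intensity
#'
#' Replaces hole pixels by the mean of the non-hole pixels, rounded half-up
#' to the nearest integer; non-hole pixels are untouched. Filling removes the
#' strong intensity step at hole borders before ridge filtering.
#'
#' @param plane numeric H x W matrix.
#' @param holes logical hole mask from [detectTissueHoles()].
#' @return matrix with holes filled.
#' @export
fillHolesWithMean <- function(plane, holes) {
  stopIfNotMask(holes)
  if (!identical(dim(plane), dim(holes)))
    stop("plane and hole mask dimensions differ")
  if (!any(holes)) return(plane)
  if (all(holes)) stop("degenerate image: holes cover the entire plane")
  plane[holes] <- roundHalfUp(mean(plane[!holes]))
  plane
}

# sampled Gaussian and its (zero-sum) second derivative, sd = scale px
gaussianKernel1d <- function(scale, order = 0) {
  half <- max(1L, as.integer(ceiling(4 * scale)))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * scale^2))
  if (order == 0) return(g / sum(g))
  g2 <- (x^2 - scale^2) / scale^4 * g
  g2 - mean(g2)              # exact zero response on constant input
}

# raw (unnormalized) ridge response: sign-inverted second-order
# Gaussian-scaled derivative along `axis`, Gaussian-smoothed across it
rawRidgeResponse <- function(plane, axis, scale) {
  g <- gaussianKernel1d(scale, 0)
  g2 <- gaussianKernel1d(scale, 2)
  k <- if (axis == "y") outer(g2, g) else outer(g, g2)
  -as.matrix(EBImage::filter2(plane, k, boundary = "replicate"))
}

# raw response amplitude of the faintest ridge considered real: a 1-px line
# of the given contrast at the configured scale (computed on a synthetic
# template, so the floor adapts to the kernel's scaling)
minRidgeAmplitude <- function(scale, contrast) {
  n <- 2L * as.integer(ceiling(4 * scale)) + 9L
  template <- matrix(0, n, n)
  template[(n + 1L) %/% 2L, ] <- contrast
  max(rawRidgeResponse(template, "y", scale))
}

#' Ridge response of a plane
#'
#' Second-order Gaussian-scaled derivative along one axis (convolution with
#' a derivative-of-Gaussian kernel of standard deviation \code{scale},
#' smoothed with a plain Gaussian along the other axis), sign-inverted so
#' that bright curvilinear structures give positive response, then min-max
#' normalized to [0, 1]. A constant plane returns an all-zero response.
#' \code{axis = "y"} differentiates across rows and therefore responds to
#' horizontal fibers; \code{axis = "x"} responds to vertical ones.
#'
#' @param plane numeric H x W matrix.
#' @param axis "x" (across columns) or "y" (across rows).
#' @param scale Gaussian standard deviation in pixels, > 0.
#' @return numeric matrix with values in [0, 1].
#' @export
ridgeResponse <- function(plane, axis = c("x", "y"), scale = 1) {
  axis <- match.arg(axis)
  if (scale <= 0) stop("scale must be > 0")
  normalizeResponse(rawRidgeResponse(plane, axis, scale))
}

normalizeResponse <- function(r) {
  rng <- range(r)
  if (diff(rng) < 1e-9) return(matrix(0, nrow(r), ncol(r)))
  (r - rng[1]) / diff(rng)
}

#' Threshold a normalized ridge response
#'
#' A pixel is detected when its response is positive and at least
#' \code{1 - sensitivity}: sensitivity 0 keeps only the strongest response,
#' sensitivity 1 keeps every positive response.
#'
#' @param resp numeric matrix in [0, 1] from [ridgeResponse()].
#' @param sensitivity detection leniency in [0, 1].
#' @return logical matrix.
#' @export
binarizeResponse <- function(resp, sensitivity) {
  if (sensitivity < 0 || sensitivity > 1)
    stop("sensitivity must lie in [0, 1]")
  resp >= (1 - sensitivity) & resp > 0
}

#' Trace axons inside a region of interest
#'
#' The full detection pipeline on one plane: crop to the region, identify
#' and fill tissue holes, compute x- and y-axis ridge responses, binarize at
#' the configured sensitivity, combine, skeletonize, remove small particles,
#' and measure. The total length is the number of surviving skeleton pixels.
#' An empty region, or a degenerate plane with no tissue, yields a zero
#' length result rather than an error so that batch runs keep going.
#'
#' @param plane numeric H x W matrix (axon channel) on the 0-255 scale.
#' @param roi a [RoiMask-class].
#' @param p a [DetectionParams-class].
#' @param detail if \code{TRUE}, per-axon records are attached (one per
#'   8-connected skeleton component).
#' @return a [TraceResult-class].
#' @export
traceAxons <- function(plane, roi, p = detectionParams(), detail = FALSE) {
  if (!any(roi@mask)) {
    return(new("TraceResult", skeleton = matrix(FALSE, 0, 0),
               cropOffset = c(1L, 1L), totalLengthPx = 0,
               normalizedLength = NULL,
               axons = if (detail) emptyAxonTable() else NULL))
  }
  cr <- applyRoiAndCrop(plane, roi)
  work <- cr$plane
  zeroResult <- function() {
    new("TraceResult",
        skeleton = matrix(FALSE, nrow(work), ncol(work)),
        cropOffset = as.integer(cr$offset), totalLengthPx = 0,
        normalizedLength = NULL,
        axons = if (detail) emptyAxonTable() else NULL)
  }
  if (p@holeFill) {
    holes <- tryCatch(detectTissueHoles(work, p), error = function(e) NULL)
    if (is.null(holes)) return(zeroResult())   # no tissue at all
    work <- fillHolesWithMean(work, holes)
  }
  rawX <- rawRidgeResponse(work, "x", p@derivativeScale)
  rawY <- rawRidgeResponse(work, "y", p@derivativeScale)
  # signal precondition: the normalized response always spans [0, 1], so on
  # a plane whose strongest raw response is weaker than that of the
  # faintest credible ridge (a 1-px line of minRidgeContrast levels),
  # thresholding would merely binarize amplified background noise
  if (p@minRidgeContrast > 0 &&
      max(rawX, rawY) < minRidgeAmplitude(p@derivativeScale,
                                          p@minRidgeContrast))
    return(zeroResult())
  binX <- binarizeResponse(normalizeResponse(rawX), p@sensitivity) & cr$mask
  binY <- binarizeResponse(normalizeResponse(rawY), p@sensitivity) & cr$mask
  skel <- cleanupSkeleton(extractSkeleton(binX, binY), p@cleanupPx)
  new("TraceResult", skeleton = skel, cropOffset = as.integer(cr$offset),
      totalLengthPx = sum(skel), normalizedLength = NULL,
      axons = if (detail) labelIndividualAxons(skel) else NULL)
}

emptyAxonTable <- function() {
  data.frame(component_id = integer(0), length_px = integer(0),
             color = character(0), stringsAsFactors = FALSE)
}

#' Label individual axons
#'
#' One record per 8-connected skeleton component, numbered in raster order,
#' with pixel-count length and a unique display color (evenly spaced hues in
#' component order, hence deterministic). Lengths sum exactly to the total
#' skeleton pixel count.
#'
#' @param skel logical (cleaned) skeleton matrix.
#' @return data.frame with \code{component_id}, \code{length_px},
#'   \code{color} (hex string).
#' @export
labelIndividualAxons <- function(skel) {
  stopIfNotMask(skel)
  lab <- labelComponents(skel)
  sz <- componentSizes(lab)
  if (!length(sz)) return(emptyAxonTable())
  n <- length(sz)
  data.frame(component_id = seq_len(n), length_px = as.integer(sz),
             color = hsv((seq_len(n) - 1) / n, 1, 1),
             stringsAsFactors = FALSE)
}

#' Superimpose a skeleton on an image
#'
#' Paints skeleton pixels onto an RGB frame (grayscale planes are promoted
#' to RGB first) in the trace color -- yellow for aggregate tracings, the
#' per-axon colors of [labelIndividualAxons()] in detail mode. All other
#' pixels are returned untouched.
#'
#' @param original H x W x 3 array (0-255) or H x W matrix.
#' @param skel logical skeleton matrix (cropped frame).
#' @param offset integer (row, col) of the crop origin, 1-based.
#' @param color length-3 RGB vector (0-255), default yellow; or a
#'   data.frame from [labelIndividualAxons()] for multicolor rendering, in
#'   which case \code{skel} is recolored per component.
#' @return H x W x 3 array.
#' @export
renderOverlay <- function(original, skel, offset = c(1L, 1L),
                          color = c(255, 255, 0)) {
  if (is.matrix(original)) original <- grayToRgb(original)
  stopIfNotMask(skel)
  h <- dim(original)[1]; w <- dim(original)[2]
  if (offset[1] + nrow(skel) - 1 > h || offset[2] + ncol(skel) - 1 > w)
    stop("skeleton does not fit within the original at the given offset")
  out <- original
  if (is.data.frame(color)) {
    lab <- labelComponents(skel)
    rgb <- col2rgb(color$color)
    for (i in seq_len(nrow(color))) {
      sel <- which(lab == color$component_id[i], arr.ind = TRUE)
      if (!nrow(sel)) next
      sel[, 1] <- sel[, 1] + offset[1] - 1L
      sel[, 2] <- sel[, 2] + offset[2] - 1L
      for (ch in 1:3)
        out[cbind(sel, ch)] <- rgb[ch, i]
    }
  } else {
    sel <- which(skel, arr.ind = TRUE)
    if (nrow(sel)) {
      sel[, 1] <- sel[, 1] + offset[1] - 1L
      sel[, 2] <- sel[, 2] + offset[2] - 1L
      for (ch in 1:3)
        out[cbind(sel, ch)] <- color[ch]
    }
  }
  out
}
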