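# Seeded synthetic fixtures: fluorescence-like images with bright smooth
# curves of known analytic arc length (the "axon" channel), blob-like graft
# signal with debris (the "ROI" channel), and near-zero tissue holes. All
# randomness is driven by the fixture spec's seed, so every fixture is
# reproducible byte for byte.

#' Describe a synthetic fixture
#'
#' Bundles the geometry and noise model of one synthetic image. Curves are
#' smooth, non-self-intersecting and mutually disjoint by construction, so
#' the number of traceable structures equals \code{nAxons}. Arc length is
#' accumulated analytically while the curve is generated (constant-speed
#' polyline with 0.05-px steps).
#'
#' @param imageSize integer (H, W), default c(640, 640).
#' @param nAxons number of curves, default 20.
#' @param axonWidthPx stroke width in pixels, default 3.
#' @param axonIntensity curve intensity (0-255), default 200.
#' @param axonLengthPx target arc length per curve, default 200.
#' @param backgroundMean,backgroundSd Gaussian background noise model,
#'   defaults 30 and 8.
#' @param graftBlobs list of \code{list(center = c(row, col), halfWidth)}
#'   square blobs for the ROI channel.
#' @param debrisCount,debrisSizeRange debris specks for the ROI channel.
#' @param holeRects list of \code{c(row1, col1, row2, col2)} rectangles
#'   zeroed as tissue holes.
#' @param seed integer controlling all randomness.
#' @return a \code{fixtureSpec} list.
#' @export
fixtureSpec <- function(imageSize = c(640, 640), nAxons = 20,
                        axonWidthPx = 3, axonIntensity = 200,
                        axonLengthPx = 200,
                        backgroundMean = 30, backgroundSd = 8,
                        graftBlobs = list(), debrisCount = 0,
                        debrisSizeRange = c(2, 8), holeRects = list(),
                        seed = 1) {
  structure(list(imageSize = as.integer(imageSize), nAxons = nAxons,
                 axonWidthPx = axonWidthPx, axonIntensity = axonIntensity,
                 axonLengthPx = axonLengthPx,
                 backgroundMean = backgroundMean, backgroundSd = backgroundSd,
                 graftBlobs = graftBlobs, debrisCount = debrisCount,
                 debrisSizeRange = debrisSizeRange, holeRects = holeRects,
                 seed = as.integer(seed)),
            class = "fixtureSpec")
}

# one smooth constant-speed curve: heading random walk with gentle
# curvature; returns dense polyline (step px) and exact arc length
generateCurvePoints <- function(start, heading, lengthPx, step = 0.05,
                                curvatureSd = 0.015) {
  n <- ceiling(lengthPx / step)
  dh <- rnorm(n, 0, curvatureSd * sqrt(step))
  h <- heading + cumsum(dh)
  x <- start[2] + cumsum(cos(h) * step)
  y <- start[1] + cumsum(sin(h) * step)
  list(x = c(start[2], x), y = c(start[1], y), length = n * step)
}

rasterizeCurve <- function(pts, dims, widthPx) {
  r <- pmin(pmax(round(pts$y) + 1L, 1L), dims[1])
  c <- pmin(pmax(round(pts$x) + 1L, 1L), dims[2])
  m <- matrix(FALSE, dims[1], dims[2])
  m[cbind(r, c)] <- TRUE
  if (widthPx > 1) m <- dilateByDistance(m, widthPx / 2)
  m
}

#' Generate a synthetic axon image with known ground truth
#'
#' Draws \code{nAxons} smooth random curves of known arc length, stroked at
#' \code{axonWidthPx}, over Gaussian background noise, then punches the
#' requested tissue holes. Curves keep a safety margin from the border and a
#' minimum separation from each other (rejection sampling, bounded retries),
#' so traced structures stay disjoint. The axon signal is placed in the
#' channel named by \code{axonChannel}; the other channels hold background
#' noise only (or the graft channel, see [generateGraftChannel()]).
#'
#' @param spec a [fixtureSpec()].
#' @param axonChannel "r", "g" or "b"; default "g".
#' @param withGraft if \code{TRUE}, the red channel carries
#'   [generateGraftChannel()] output.
#' @return list with \code{image} (a [MultiChannelImage-class]),
#'   \code{truth} (list: \code{axonLengths}, \code{totalLength},
#'   \code{axonMask}, \code{graftMask}, \code{holeMask}).
#' @export
generateAxonImage <- function(spec, axonChannel = "g", withGraft = FALSE) {
  set.seed(spec$seed)
  dims <- spec$imageSize
  margin <- 25
  sep <- 12
  occupied <- matrix(FALSE, dims[1], dims[2])
  axonMask <- matrix(FALSE, dims[1], dims[2])
  lengths <- numeric(0)
  if (spec$nAxons > 0) {
    for (i in seq_len(spec$nAxons)) {
      placed <- FALSE
      for (try in 1:400) {
        start <- c(runif(1, margin, dims[1] - margin),
                   runif(1, margin, dims[2] - margin))
        heading <- runif(1, 0, 2 * pi)
        pts <- generateCurvePoints(start, heading, spec$axonLengthPx)
        if (min(pts$x) < margin || max(pts$x) > dims[2] - margin ||
            min(pts$y) < margin || max(pts$y) > dims[1] - margin) next
        stroke <- rasterizeCurve(pts, dims, spec$axonWidthPx)
        if (any(stroke & occupied)) next
        axonMask <- axonMask | stroke
        occupied <- occupied | dilateByDistance(stroke, sep)
        lengths <- c(lengths, pts$length)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place curve ", i, " without overlap; ",
             "reduce nAxons or enlarge the image")
    }
  }
  noise <- function() {
    matrix(clamp255(round(rnorm(prod(dims), spec$backgroundMean,
                                spec$backgroundSd))), dims[1], dims[2])
  }
  axonPlane <- noise()
  axonPlane[axonMask] <- spec$axonIntensity
  graftMask <- matrix(FALSE, dims[1], dims[2])
  graftPlane <- NULL
  if (withGraft) {
    g <- generateGraftChannelPlane(spec)
    graftPlane <- g$plane
    graftMask <- g$mask
  }
  holeMask <- matrix(FALSE, dims[1], dims[2])
  for (rect in spec$holeRects) {
    holeMask[rect[1]:rect[3], rect[2]:rect[4]] <- TRUE
  }
  axonPlane[holeMask] <- 0
  planes <- list(r = NULL, g = NULL, b = NULL)
  planes[[axonChannel]] <- axonPlane
  if (withGraft && axonChannel != "r") planes$r <- graftPlane
  for (ch in c("r", "g", "b"))
    if (is.null(planes[[ch]])) planes[[ch]] <- noise()
  pixels <- array(0, c(dims, 3L))
  pixels[, , 1] <- planes$r; pixels[, , 2] <- planes$g
  pixels[, , 3] <- planes$b
  img <- new("MultiChannelImage", pixels = pixels,
             entry = list(numeric_id = 1L, path = NA_character_,
                          format = "tiff"))
  list(image = img,
       truth = list(axonLengths = lengths, totalLength = sum(lengths),
                    axonMask = axonMask, graftMask = graftMask,
                    holeMask = holeMask))
}

generateGraftChannelPlane <- function(spec) {
  dims <- spec$imageSize
  plane <- matrix(clamp255(round(rnorm(prod(dims), 10, 4))),
                  dims[1], dims[2])
  mask <- matrix(FALSE, dims[1], dims[2])
  for (b in spec$graftBlobs) {
    ctr <- b$center; hw <- b$halfWidth
    rows <- max(1, ctr[1] - hw):min(dims[1], ctr[1] + hw)
    cols <- max(1, ctr[2] - hw):min(dims[2], ctr[2] + hw)
    mask[rows, cols] <- TRUE
  }
  plane[mask] <- 200
  if (spec$debrisCount > 0) {
    for (i in seq_len(spec$debrisCount)) {
      sz <- sample(spec$debrisSizeRange[1]:spec$debrisSizeRange[2], 1)
      side <- max(1L, round(sqrt(sz)))
      r0 <- sample(dims[1] - side, 1); c0 <- sample(dims[2] - side, 1)
      plane[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 180
    }
  }
  list(plane = plane, mask = mask)
}

#' Generate a graft (ROI) channel
#'
#' Bright square blobs at the specified centers and half-widths, plus seeded
#' debris specks over dim background noise. The truth mask covers the blobs
#' only, never the debris.
#'
#' @param spec a [fixtureSpec()] with \code{graftBlobs} (and optionally
#'   \code{debrisCount}).
#' @return list with \code{plane} (0-255 matrix) and \code{mask} (logical
#'   truth).
#' @export
generateGraftChannel <- function(spec) {
  set.seed(spec$seed)
  generateGraftChannelPlane(spec)
}

#' Punch rectangular tissue holes into a plane or image
#'
#' Sets the listed rectangles (1-based \code{c(row1, col1, row2, col2)}) to
#' intensity zero, emulating holes in sectioned tissue.
#'
#' @param x numeric matrix or H x W x 3 array.
#' @param holeRects list of rectangles.
#' @return same type as \code{x}.
#' @export
punchHoles <- function(x, holeRects) {
  for (rect in holeRects) {
    if (is.matrix(x)) {
      x[rect[1]:rect[3], rect[2]:rect[4]] <- 0
    } else {
      x[rect[1]:rect[3], rect[2]:rect[4], ] <- 0
    }
  }
  x
}

#' Write a fixture analysis folder
#'
#' Generates one image per spec and writes them in the exact layout
#' [scanAnalysisFolder()] expects: numeric filenames, images only.
#'
#' @param specs list of [fixtureSpec()] objects.
#' @param dir target directory (created if needed).
#' @param ids numeric filenames to use; default \code{seq_along(specs)}.
#' @param format "tiff" or "png".
#' @param axonChannel,withGraft passed to [generateAxonImage()].
#' @return data.frame of truths, one row per image (\code{numeric_id},
#'   \code{totalLength}, \code{nAxons}).
#' @export
writeFixtureFolder <- function(specs, dir, ids = seq_along(specs),
                               format = "tiff", axonChannel = "g",
                               withGraft = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- c(tiff = "tiff", png = "png")[[format]]
  truths <- lapply(seq_along(specs), function(i) {
    gen <- generateAxonImage(specs[[i]], axonChannel = axonChannel,
                             withGraft = withGraft)
    writeRgbImage(gen$image@pixels,
                  file.path(dir, paste0(ids[i], ".", ext)))
    data.frame(numeric_id = ids[i], totalLength = gen$truth$totalLength,
               nAxons = length(gen$truth$axonLengths))
  })
  do.call(rbind, truths)
}
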