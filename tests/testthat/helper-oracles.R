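# Independent oracles used to check pipeline operations. These are written
# for clarity, not speed, and deliberately share no code with the package
# internals.

# brute-force connected-component labelling by queue flood fill
bruteLabel <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    offs <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nextLab <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nextLab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nextLab
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
  }
  lab
}

# exhaustive-search Otsu threshold: maximize between-class variance over all
# 256 candidate thresholds on 0-255 data
bruteOtsu <- function(values) {
  best <- -Inf; bestT <- 0
  for (t in 0:254) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    wb <- length(lo) / length(values)
    v <- wb * (1 - wb) * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; bestT <- t }
  }
  bestT
}

# brute-force Euclidean distance of every pixel to the nearest TRUE pixel
bruteDistanceTo <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  d <- matrix(Inf, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    d[r, c] <- sqrt(min((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
  }
  d
}

# brute-force inclusive point-in-polygon over every pixel (0-based verts)
brutePolygonMask <- function(vx, vy, h, w) {
  n <- length(vx)
  onSegment <- function(px, py, x1, y1, x2, y2) {
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) > 1e-9) return(FALSE)
    px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
      py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9
  }
  m <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    px <- c - 1; py <- r - 1
    inside <- FALSE; edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if (onSegment(px, py, vx[j], vy[j], vx[i], vy[i])) { edge <- TRUE }
      if ((vy[j] > py) != (vy[i] > py)) {
        xint <- vx[j] + (py - vy[j]) * (vx[i] - vx[j]) / (vy[i] - vy[j])
        if (px < xint) inside <- !inside
      }
      j <- i
    }
    m[r, c] <- inside || edge
  }
  m
}

# random binary matrix with a controlled fill fraction
randomMask <- function(h, w, fill = 0.3) {
  matrix(runif(h * w) < fill, h, w)
}

# two-blob binary ROI-channel plane: blobs of `side` px separated by `gap`
# empty columns, with `margin` background on every side
twoBlobPlane <- function(gap, side = 300, margin = 150, fg = 200) {
  h <- side + 2 * margin
  w <- 2 * side + gap + 2 * margin
  p <- matrix(0, h, w)
  rows <- margin + seq_len(side)
  p[rows, margin + seq_len(side)] <- fg
  p[rows, margin + side + gap + seq_len(side)] <- fg
  p
}

# centred isolated square of half-width hw in a frame with enough margin
centredSquareMask <- function(hw, margin = 65) {
  d <- 2L * (hw + margin) + 1L
  m <- matrix(FALSE, d, d)
  ctr <- hw + margin + 1L
  m[(ctr - hw):(ctr + hw), (ctr - hw):(ctr + hw)] <- TRUE
  m
}

# detection parameters accepted for the synthetic fixture class (tuned once
# on a parameter image, then frozen for every batch/test)
fixtureDetectionParams <- function(sensitivity = 0.42,
                                   derivativeScale = 1.7,
                                   cleanupPx = 20, ...) {
  detectionParams(sensitivity = sensitivity,
                  derivativeScale = derivativeScale,
                  cleanupPx = cleanupPx, ...)
}

# small analysis folder of generated fixtures; returns list(dir, truth)
makeFixtureFolder <- function(ids = c(3L, 24L, 87L), nAxons = 3,
                              imageSize = c(256, 256), seedBase = 100,
                              withGraft = FALSE, format = "tiff") {
  dir <- tempfile("folder")
  specs <- lapply(seq_along(ids), function(i) {
    fixtureSpec(imageSize = imageSize, nAxons = nAxons, axonLengthPx = 120,
                seed = seedBase + i,
                graftBlobs = if (withGraft)
                  list(list(center = c(128, 110), halfWidth = 60)) else list())
  })
  truth <- writeFixtureFolder(specs, dir, ids = ids, format = format,
                              withGraft = withGraft)
  list(dir = dir, truth = truth)
}
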