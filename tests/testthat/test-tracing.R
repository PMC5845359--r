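# ROI application, tissue-hole repair, ridge filtering and the full
# trace pipeline.

test_that("applyRoiAndCrop produces a tight masked crop", {
  plane <- matrix(seq_len(1000 * 1000) %% 251, 1000, 1000)
  m <- matrix(FALSE, 1000, 1000)
  m[100:199, 200:299] <- TRUE
  cr <- applyRoiAndCrop(plane, roiMask(m))
  expect_equal(dim(cr$plane), c(100, 100))
  expect_equal(cr$offset, c(100, 200))
  expect_identical(cr$plane, plane[100:199, 200:299])

  full <- roiMask(matrix(TRUE, 20, 30))
  cr2 <- applyRoiAndCrop(plane[1:20, 1:30], full)
  expect_identical(cr2$plane, plane[1:20, 1:30])
  expect_equal(cr2$offset, c(1, 1))

  expect_error(applyRoiAndCrop(plane, roiMask(matrix(FALSE, 1000, 1000))),
               "empty ROI")
})

test_that("applyRoiAndCrop zeroes pixels outside an irregular region", {
  plane <- matrix(100, 50, 50)
  m <- matrix(FALSE, 50, 50)
  m[which(outer((1:50) - 25, (1:50) - 25,
                function(a, b) a^2 + b^2) <= 100)] <- TRUE
  cr <- applyRoiAndCrop(plane, roiMask(m))
  expect_true(all(cr$plane[!cr$mask] == 0))
  expect_true(all(cr$plane[cr$mask] == 100))
})

test_that("detectTissueHoles flags large dark regions only", {
  p <- detectionParams(holeIntensityMax = 5, holeMinAreaPx = 500)
  plane <- matrix(100, 200, 200)
  plane[50:99, 50:99] <- 0                 # 2500-px hole
  plane[150:154, 150:154] <- 0             # 25-px dark speck, below area
  holes <- detectTissueHoles(plane, p)
  want <- matrix(FALSE, 200, 200); want[50:99, 50:99] <- TRUE
  expect_identical(holes, want)
  # brute-force oracle agreement
  lab <- bruteLabel(plane <= 5, 8)
  sizes <- tabulate(lab[lab > 0])
  oracle <- matrix(lab > 0 & lab %in% which(sizes >= 500), 200, 200)
  expect_identical(holes, oracle)

  expect_false(any(detectTissueHoles(matrix(100, 50, 50), p)))
  expect_error(detectTissueHoles(matrix(0, 50, 50), p), "degenerate")
})

test_that("fillHolesWithMean fills with the rounded non-hole mean", {
  plane <- matrix(100, 60, 60)
  holes <- matrix(FALSE, 60, 60); holes[10:29, 10:29] <- TRUE
  plane[holes] <- 0
  out <- fillHolesWithMean(plane, holes)
  expect_true(all(out[holes] == 100))
  expect_true(all(out[!holes] == plane[!holes]))
  expect_identical(fillHolesWithMean(plane, matrix(FALSE, 60, 60)), plane)
  expect_error(fillHolesWithMean(plane, matrix(TRUE, 60, 60)), "degenerate")
})

test_that("hole fill rounds half-up", {
  plane <- matrix(c(99, 100, 0, 0), 2, 2)   # non-hole mean 99.5
  holes <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  out <- fillHolesWithMean(plane, holes)
  expect_equal(out[holes], c(100, 100))
})

test_that("ridgeResponse matches a direct convolution oracle", {
  set.seed(17)
  plane <- matrix(round(runif(30 * 34) * 255), 30, 34)
  scale <- 1.5
  # oracle: explicit O(n^2) convolution with the sampled kernel, replicate
  # padding, then the same sign flip and min-max normalization
  half <- ceiling(4 * scale)
  x <- -half:half
  g <- exp(-x^2 / (2 * scale^2)); g <- g / sum(g)
  g2 <- (x^2 - scale^2) / scale^4 * exp(-x^2 / (2 * scale^2))
  g2 <- g2 - mean(g2)
  k <- outer(g2, g)                         # y-axis kernel
  conv <- matrix(0, 30, 34)
  for (r in 1:30) for (c in 1:34) {
    acc <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) {
      rr <- min(max(r + x[i], 1), 30)
      cc <- min(max(c + x[j], 1), 34)
      acc <- acc + plane[rr, cc] * k[i, j]
    }
    conv[r, c] <- acc
  }
  oracle <- -conv
  oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  got <- ridgeResponse(plane, "y", scale)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("ridgeResponse basic geometry", {
  expect_true(all(ridgeResponse(matrix(40, 50, 50), "x") == 0))
  line <- matrix(0, 50, 50); line[25, 10:40] <- 200
  ry <- ridgeResponse(line, "y")
  rx <- ridgeResponse(line, "x")
  # y response peaks on the line; x response stays flat along its interior
  expect_true(all(ry[25, 15:35] > 0.9))
  expect_true(all(abs(rx[25, 20:30] - rx[25, 25]) < 0.05))
  expect_error(ridgeResponse(line, "y", scale = 0), "scale")
})

test_that("binarizeResponse thresholds at 1 - sensitivity", {
  resp <- matrix(c(0, 0.2, 0.6, 0.9, 1), 1, 5)
  expect_equal(as.vector(binarizeResponse(resp, 0.5)),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(as.vector(binarizeResponse(resp, 1)),
               c(FALSE, TRUE, TRUE, TRUE, TRUE))   # every positive response
  expect_equal(as.vector(binarizeResponse(resp, 0)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(binarizeResponse(resp, 1.2), "sensitivity")
})

test_that("traceAxons recovers a single curve within 10%", {
  gen <- generateAxonImage(fixtureSpec(imageSize = c(300, 300), nAxons = 1,
                                       axonLengthPx = 200, seed = 14))
  planes <- splitChannels(gen$image, channelAssignment())
  roi <- roiMask(matrix(TRUE, 300, 300), "entire_image")
  tr <- traceAxons(planes$axon1, roi, fixtureDetectionParams())
  expect_equal(totalLength(tr), 200, tolerance = 0.1)
})

test_that("traceAxons on a blank plane finds nothing", {
  roi <- roiMask(matrix(TRUE, 120, 120), "entire_image")
  tr <- traceAxons(matrix(30, 120, 120), roi, fixtureDetectionParams())
  expect_equal(totalLength(tr), 0)
  # all-zero plane: degenerate, still zero length rather than an error
  tr0 <- traceAxons(matrix(0, 120, 120), roi, fixtureDetectionParams())
  expect_equal(totalLength(tr0), 0)
})

test_that("traceAxons with an empty ROI reports zero length", {
  tr <- traceAxons(matrix(100, 50, 50), roiMask(matrix(FALSE, 50, 50)),
                   fixtureDetectionParams(), detail = TRUE)
  expect_equal(totalLength(tr), 0)
  expect_equal(nrow(axonTable(tr)), 0)
})

test_that("hole filling suppresses false traces at hole edges", {
  spec <- fixtureSpec(imageSize = c(320, 320), nAxons = 0, seed = 31,
                      holeRects = list(c(80, 80, 160, 170),
                                       c(220, 40, 280, 120)))
  gen <- generateAxonImage(spec)
  planes <- splitChannels(gen$image, channelAssignment())
  roi <- roiMask(matrix(TRUE, 320, 320), "entire_image")
  withFill <- traceAxons(planes$axon1, roi, fixtureDetectionParams())
  noFill <- traceAxons(planes$axon1, roi,
                       fixtureDetectionParams(holeFill = FALSE))
  expect_equal(totalLength(withFill), 0)
  expect_gt(totalLength(noFill), 0)
})

test_that("skeleton stays inside the ROI", {
  gen <- generateAxonImage(fixtureSpec(imageSize = c(300, 300), nAxons = 2,
                                       axonLengthPx = 150, seed = 52))
  planes <- splitChannels(gen$image, channelAssignment())
  m <- matrix(FALSE, 300, 300); m[40:260, 40:260] <- TRUE
  tr <- traceAxons(planes$axon1, roiMask(m), fixtureDetectionParams())
  cropMask <- m[40:260, 40:260]
  expect_false(any(skeleton(tr) & !cropMask))
})

test_that("detection is monotone in sensitivity and cleanup", {
  gen <- generateAxonImage(fixtureSpec(imageSize = c(300, 300), nAxons = 3,
                                       axonLengthPx = 120, seed = 63))
  planes <- splitChannels(gen$image, channelAssignment())
  roi <- roiMask(matrix(TRUE, 300, 300), "entire_image")
  # binarized detection grows with sensitivity (exact set inclusion);
  # skeleton pixel counts after thinning are only approximately monotone
  # because a wider band can thin to a marginally different line
  resp <- ridgeResponse(planes$axon1, "y", 1.7)
  sets <- lapply(c(0.2, 0.42, 0.6, 0.8), function(s)
    binarizeResponse(resp, s))
  for (i in 1:3)
    expect_false(any(sets[[i]] & !sets[[i + 1]]))
  # total length is non-increasing in the cleanup size (exact)
  lens2 <- vapply(c(0, 10, 40, 120), function(cl)
    totalLength(traceAxons(planes$axon1, roi,
                           fixtureDetectionParams(cleanupPx = cl))),
    numeric(1))
  expect_true(all(diff(lens2) <= 0))
  # and within the workable sensitivity range, longer at higher sensitivity
  lens <- vapply(c(0.3, 0.5), function(s)
    totalLength(traceAxons(planes$axon1, roi,
                           fixtureDetectionParams(sensitivity = s))),
    numeric(1))
  expect_lte(lens[1], lens[2] * 1.05)
})

test_that("labelIndividualAxons conserves length and colors distinctly", {
  m <- matrix(FALSE, 60, 120)
  m[10, 3:50] <- TRUE                     # 48 px
  m[30, 10:89] <- TRUE                    # 80 px
  m[50:55, 100] <- TRUE                   # 6 px
  ax <- labelIndividualAxons(m)
  expect_equal(nrow(ax), 3)
  expect_setequal(ax$length_px, c(48L, 80L, 6L))
  expect_equal(sum(ax$length_px), sum(m))
  expect_equal(anyDuplicated(ax$color), 0L)
  expect_equal(nrow(labelIndividualAxons(matrix(FALSE, 5, 5))), 0)
  one <- labelIndividualAxons(m & row(m) == 10)
  expect_equal(one$length_px, 48L)
})

test_that("renderOverlay recolors exactly the skeleton pixels", {
  orig <- array(round(runif(40 * 50 * 3) * 255), c(40, 50, 3))
  sk <- matrix(FALSE, 10, 10); sk[3, 2:8] <- TRUE; sk[7, 4] <- TRUE
  out <- renderOverlay(orig, sk, offset = c(11L, 21L))
  diff <- which(out != orig, arr.ind = TRUE)
  touched <- unique(diff[, 1:2, drop = FALSE])
  expect_lte(nrow(touched), sum(sk))
  sel <- which(sk, arr.ind = TRUE)
  sel[, 1] <- sel[, 1] + 10L; sel[, 2] <- sel[, 2] + 20L
  for (k in seq_len(nrow(sel)))
    expect_equal(out[sel[k, 1], sel[k, 2], ], c(255, 255, 0))
  # empty skeleton changes nothing
  expect_identical(renderOverlay(orig, matrix(FALSE, 10, 10)), orig)
  expect_error(renderOverlay(orig, matrix(TRUE, 50, 50)), "fit")
})

test_that("detail-mode overlay uses one distinct color per component", {
  sk <- matrix(FALSE, 30, 30)
  sk[5, 2:20] <- TRUE; sk[15, 5:25] <- TRUE; sk[25, 10:14] <- TRUE
  ax <- labelIndividualAxons(sk)
  out <- renderOverlay(matrix(0, 30, 30), sk, c(1L, 1L), ax)
  cols <- unique(apply(which(sk, arr.ind = TRUE), 1, function(p)
    paste(out[p[1], p[2], ], collapse = "-")))
  expect_equal(length(cols), 3)
})
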